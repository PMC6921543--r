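#' Published macrophage activation networks
#'
#' The three published Boolean networks for LPS-induced M1, IL-4-induced
#' M2a and IL-10-induced M2c macrophage activation, encoded verbatim from
#' their printed rule tables: per-child Boolean functions, LP interaction
#' weights, node attribution (input / intermediate state / output), the
#' core-network node lists, and the printed core state trajectories with
#' their delta indices. Greek letters in protein names are transliterated
#' (IFN-g, IL-1a, MIP-1b, TNF-a).
#'
#' Known discrepancies in the printed tables are preserved, not repaired:
#' the M1 table enumerates 38 parent entries while the printed summary
#' counts 39 links (and one two-parent rule carries a single printed
#' weight), and a few rows' weight signs contradict the printed literal
#' polarity. Weight-based counts therefore use the weights as printed.
#'
#' @param name `"M1"`, `"M2a"` or `"M2c"`.
#' @return a list with `name`, `stimulus`, `network` ([boolean_network()]),
#'   `rules` (data.frame: child, expression, attribution), `weights` (list
#'   per child), `links` (data.frame parent/child/weight usable by
#'   [network_metrics()]), `core_nodes`, `core_network` (restriction of
#'   the rules to the core nodes, where well defined, else NULL),
#'   `collapsed_core` (M2c only: the 5-node delay-free core), `state_table`
#'   (printed core states: matrix with delta-index rownames), `trajectory`
#'   (printed delta-index path), `fixed_points` (published stable states).
#' @export
macrophage_fixture <- function(name = c("M1", "M2a", "M2c")) {
  name <- match.arg(name)
  switch(name, M1 = fixture_m1(), M2a = fixture_m2a(), M2c = fixture_m2c())
}

fixture_rule_df <- function(...) {
  rows <- list(...)
  data.frame(child = vapply(rows, `[[`, character(1), 1),
             expression = vapply(rows, `[[`, character(1), 2),
             attribution = vapply(rows, `[[`, character(1), 3),
             stringsAsFactors = FALSE)
}

fixture_network <- function(rules_df, weights) {
  rules <- list()
  for (i in seq_len(nrow(rules_df))) {
    child <- rules_df$child[i]
    expr <- rules_df$expression[i]
    rules[[child]] <- if (expr == "<input>") bn_rule(character(0), integer(0))
                      else parse_rule(expr)
  }
  bn <- boolean_network(rules)
  links <- list()
  for (child in names(weights)) {
    w <- weights[[child]]
    parents <- bn$rules[[child]]$parents
    np <- length(parents)
    if (length(w) < np) w <- c(w, rep(NA_real_, np - length(w)))
    links[[child]] <- data.frame(parent = parents, child = child,
                                 weight = w[seq_len(np)])
  }
  links <- do.call(rbind, c(links, make.row.names = FALSE))
  list(network = bn, links = links)
}

fixture_m1 <- function() {
  rules_df <- fixture_rule_df(
    list("FGF-9", "<input>", "Input"),
    list("GM-CSF", "!IFN-g & MCP-5", "Output"),
    list("KC-GRO", "IL-10 & !MCP-5", "IS"),
    list("IFN-g", "SCF | IFN-g", "IS"),
    list("IP-10", "IL-10 & MCP-5", "Output"),
    list("IL-1a", "Lymphotactin", "IS"),
    list("IL-2", "(!KC-GRO & !MIP-2) | (KC-GRO & !RANTES)", "Output"),
    list("IL-3", "SCF", "IS"),
    list("IL-4", "<input>", "Input"),
    list("IL-6", "IL-1a & !RANTES", "Output"),
    list("IL-7", "MIP-1b", "Output"),
    list("IL-10", "!IL-4 & Lymphotactin", "IS"),
    list("IL-11", "FGF-9", "IS"),
    list("IL-12p70", "MCP-5", "Output"),
    list("IL-17A", "MCP-5", "Output"),
    list("Lymphotactin", "!IFN-g", "IS"),
    list("MIP-1b", "IL-3 | IL-11", "IS"),
    list("MIP-2", "IL-10 & !MIP-1b", "IS"),
    list("MCP-1", "!IFN-g", "IS"),
    list("MCP-3", "(IL-4 & FGF-9) | (!FGF-9 & !RANTES)", "IS"),
    list("MCP-5", "Lymphotactin & MCP-1", "IS"),
    list("OSM", "IL-10 & MIP-1b", "Output"),
    list("SCF", "!IL-1a", "IS"),
    list("RANTES", "!MCP-3", "IS"),
    list("TNF-a", "!IL-1a", "Output"),
    list("VEGF-A", "!MCP-5", "Output"))
  weights <- list(
    "GM-CSF" = c(-180, 185), "KC-GRO" = c(5.45, -5.82), "IFN-g" = c(1170),
    "IP-10" = c(68100, 85000), "IL-1a" = c(787000),
    "IL-2" = c(34.7, -27, -33.8), "IL-3" = c(302), "IL-6" = c(3840, -4840),
    "IL-7" = c(10), "IL-10" = c(-64700, 48600), "IL-11" = c(6190),
    "IL-12p70" = c(5.6), "IL-17A" = c(0.555), "Lymphotactin" = c(-1675),
    "MIP-1b" = c(44800, 41600), "MIP-2" = c(7880, -10400),
    "MCP-1" = c(-5090), "MCP-3" = c(27600, 22800, -27400),
    "MCP-5" = c(5840, -4590), "OSM" = c(6.45, 6.19), "SCF" = c(-70800),
    "RANTES" = c(304), "TNF-a" = c(-1.37), "VEGF-A" = c(-17850))
  fx <- fixture_network(rules_df, weights)
  core_nodes <- c("MCP-5", "Lymphotactin", "IL-1a", "SCF", "IFN-g", "MCP-1")
  core_network <- boolean_network(fx$network$rules[core_nodes],
                                  nodes = core_nodes)
  state_table <- rbind(
    "11" = c(1, 1, 0, 1, 0, 1),
    "1"  = c(1, 1, 1, 1, 1, 1),
    "22" = c(1, 0, 1, 0, 1, 0),
    "62" = c(0, 0, 0, 0, 1, 0),
    "58" = c(0, 0, 0, 1, 1, 0))
  colnames(state_table) <- core_nodes
  list(name = "M1", stimulus = "LPS", network = fx$network,
       nodes = fx$network$nodes,
       rules = rules_df, weights = weights, links = fx$links,
       core_nodes = core_nodes, core_network = core_network,
       collapsed_core = NULL, state_table = state_table,
       trajectory = c(11L, 1L, 22L, 62L, 58L),
       fixed_points = c(7L, 58L),
       sub_network_nodes = c("MCP-3", "RANTES"))
}

fixture_m2a <- function() {
  rules_df <- fixture_rule_df(
    list("FGF-9", "(!MIP-2 & !VEGF-A) | (MIP-2 & VEGF-A) | (!MIP-2 & Lymphotactin)", "IS"),
    list("GM-CSF", "!MCP-1 | SCF", "Output"),
    list("IFN-g", "MIP-2 | !VEGF-A", "IS"),
    list("IP-10", "VEGF-A", "IS"),
    list("IL-1a", "<input>", "Input"),
    list("IL-2", "MCP-3", "IS"),
    list("IL-3", "MCP-3", "Output"),
    list("IL-4", "MCP-1", "Output"),
    list("IL-6", "Lymphotactin", "Output"),
    list("IL-7", "IL-1a & MCP-5", "Output"),
    list("IL-10", "VEGF-A", "IS"),
    list("IL-12p70", "Lymphotactin", "Output"),
    list("IL-17A", "MCP-3", "Output"),
    list("Lymphotactin", "IL-1a & MCP-5", "IS"),
    list("MIP-1b", "IL-1a & MCP-1", "IS"),
    list("MIP-2", "MCP-3 & MCP-5", "IS"),
    list("MCP-1", "!IL-2 & !MIP-1b", "IS"),
    list("MCP-3", "IFN-g & MCP-1", "IS"),
    list("MCP-5", "SCF | !VEGF-A", "IS"),
    list("OSM", "MCP-1", "Output"),
    list("SCF", "FGF-9 & IL-10", "IS"),
    list("TIMP-1", "Lymphotactin", "Output"),
    list("TNF-a", "IL-2", "Output"),
    list("VEGF-A", "MCP-5 & SCF", "IS"))
  weights <- list(
    "FGF-9" = c(89.6, 87, -82), "GM-CSF" = c(2.75, -3.23),
    "IFN-g" = c(34, -31.7), "IP-10" = c(121), "IL-2" = c(92.7),
    "IL-3" = c(41.9), "IL-4" = c(151), "IL-6" = c(58.7),
    "IL-7" = c(-0.9, -1), "IL-10" = c(-296), "IL-12p70" = c(0.557),
    "IL-17A" = c(0.34), "Lymphotactin" = c(192, -159),
    "MIP-1b" = c(-6490, 6650), "MIP-2" = c(816, -1160),
    "MCP-1" = c(-6150, -6520), "MCP-3" = c(-15900, 16800),
    "MCP-5" = c(1300, -1140), "OSM" = c(1.11), "SCF" = c(12700, -14400),
    "TIMP-1" = c(1.19), "TNF-a" = c(-0.188), "VEGF-A" = c(-13400, 13300))
  fx <- fixture_network(rules_df, weights)
  core_nodes <- c("VEGF-A", "FGF-9", "MIP-1b", "MCP-5", "SCF", "MIP-2", "MCP-1")
  state_table <- rbind(
    "3"   = c(1, 1, 1, 1, 1, 0, 1),
    "4"   = c(1, 1, 1, 1, 1, 0, 0),
    "20"  = c(1, 1, 0, 1, 1, 0, 0),
    "84"  = c(0, 1, 0, 1, 1, 0, 0),
    "120" = c(0, 0, 0, 1, 0, 0, 0),
    "88"  = c(0, 1, 0, 1, 0, 0, 0))
  colnames(state_table) <- core_nodes
  list(name = "M2a", stimulus = "IL-4", network = fx$network,
       nodes = fx$network$nodes,
       rules = rules_df, weights = weights, links = fx$links,
       core_nodes = core_nodes, core_network = NULL,
       collapsed_core = NULL, state_table = state_table,
       trajectory = c(3L, 4L, 20L, 84L, 120L),
       fixed_points = c(88L, 1L),
       input_nodes = "IL-1a")
}

fixture_m2c <- function() {
  rules_df <- fixture_rule_df(
    list("FGF-9", "MIP-1b", "IS"),
    list("GM-CSF", "!IP-10 & !IL-2 & IL-4 & IL-10", "Output"),
    list("IFN-g", "IL-1a & SCF", "IS"),
    list("IP-10", "MCP-1 & MCP-3", "IS"),
    list("IL-1a", "IL-11 & MCP-3", "IS"),
    list("IL-2", "IL-10 & !IL-11", "IS"),
    list("IL-3", "FGF-9 & !IL-1a & !MCP-1 & MCP-3", "Output"),
    list("IL-4", "IL-10", "IS"),
    list("IL-6", "IL-1a & MIP-1b & !MIP-2 & !VEGF-A", "Output"),
    list("IL-7", "MCP-3", "Output"),
    list("IL-10", "MCP-3", "IS"),
    list("IL-11", "IL-1a", "IS"),
    list("IL-12p70", "MCP-3 | !SCF", "Output"),
    list("IL-17A", "!MCP-1 | MCP-3", "Output"),
    list("Lymphotactin", "SCF", "IS"),
    list("MIP-1b", "IL-11", "IS"),
    list("MIP-2", "SCF", "IS"),
    list("MCP-1", "MIP-1b & SCF", "IS"),
    list("MCP-3", "IFN-g", "IS"),
    list("MCP-5", "!SCF", "IS"),
    list("OSM", "MIP-1b", "Output"),
    list("SCF", "IL-11 & MCP-5", "IS"),
    list("TNF-a", "IP-10", "Output"),
    list("VEGF-A", "Lymphotactin | !MCP-5", "Output"))
  weights <- list(
    "FGF-9" = c(13), "GM-CSF" = c(-0.83, -0.73, 0.73, 0.75),
    "IFN-g" = c(-18, 20), "IP-10" = c(-4470, 4050),
    "IL-1a" = c(-699, 609), "IL-2" = c(5.62, -6.42),
    "IL-3" = c(7.16, -7.99, -8.86, 8.68), "IL-4" = c(41.6),
    "IL-6" = c(2.26, 2.09, -2.4, -2.04), "IL-7" = c(0.476),
    "IL-10" = c(3330), "IL-11" = c(-78.1), "IL-12p70" = c(1.34, -1.38),
    "IL-17A" = c(-0.236, 0.19), "Lymphotactin" = c(39),
    "MIP-1b" = c(-16100), "MIP-2" = c(2420), "MCP-1" = c(2050, 1920),
    "MCP-3" = c(1410), "MCP-5" = c(-728), "OSM" = c(0.186),
    "SCF" = c(14700, -18000), "TNF-a" = c(0.156),
    "VEGF-A" = c(19200, -24100))
  fx <- fixture_network(rules_df, weights)
  core_nodes <- c("IL-11", "SCF", "MCP-5", "IL-1a", "IFN-g")
  ## delay-free collapsed core: the transduction node MCP-3 (IFN-g -> IL-1a)
  ## substituted into IL-1a's rule
  collapsed_core <- boolean_network(list(
    "IL-11" = "IL-1a",
    "SCF" = "IL-11 & MCP-5",
    "MCP-5" = "!SCF",
    "IL-1a" = "IL-11 & IFN-g",
    "IFN-g" = "IL-1a & SCF")[c("IL-11", "SCF", "MCP-5", "IL-1a", "IFN-g")])
  state_table <- rbind(
    "1"  = c(1, 1, 1, 1, 1),
    "5"  = c(1, 1, 0, 1, 1),
    "13" = c(1, 0, 0, 1, 1),
    "10" = c(1, 0, 1, 1, 0),
    "4"  = c(1, 1, 1, 0, 0),
    "24" = c(0, 1, 0, 0, 0),
    "32" = c(0, 0, 0, 0, 0),
    "28" = c(0, 0, 1, 0, 0))
  colnames(state_table) <- core_nodes
  list(name = "M2c", stimulus = "IL-10", network = fx$network,
       nodes = fx$network$nodes,
       rules = rules_df, weights = weights, links = fx$links,
       core_nodes = core_nodes, core_network = NULL,
       collapsed_core = collapsed_core, state_table = state_table,
       trajectory = c(1L, 5L, 13L, 10L, 4L, 24L, 32L, 28L),
       fixed_points = 28L)
}
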