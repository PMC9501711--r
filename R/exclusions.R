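# Nonbonded exclusion classes from bond-graph topology.

#' Classify atom pairs by bonded separation
#'
#' Derives the nonbonded exclusion class of every atom pair from shortest
#' paths on the bond graph: directly bonded pairs (`excluded_12`) and pairs
#' separated by two bonds (`excluded_13`) are excluded from nonbonded
#' energy; pairs three bonds apart (`scaled_14`) interact with 1-4 scale
#' factors; everything further (or disconnected) interacts fully.
#'
#' @param mol A [molecule()].
#' @return Tibble with columns `i`, `j` (i < j, 1-based) and `class`
#'   (factor-free character: "excluded_12", "excluded_13", "scaled_14",
#'   "full"), one row per unordered pair.
#' @examples
#' build_exclusions(make_toy_ligand("butane_like"))
#' @export
build_exclusions <- function(mol) {
  n <- nrow(mol$atoms)
  g <- igraph::graph_from_edgelist(mol$bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  D <- igraph::distances(g)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  sep <- D[idx]
  cls <- ifelse(sep <= 1, "excluded_12",
         ifelse(sep == 2, "excluded_13",
         ifelse(sep == 3, "scaled_14", "full")))
  tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]), class = cls)
}
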