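#' Build the species-sample heterogeneous graph
#'
#' Assembles the typed graph from a preprocessed abundance matrix and optional
#' binary relation matrices. Nodes are species and samples; edge types are
#' `abundance` (species i -- sample j whenever a_ij > 0, weight a_ij),
#' `metabolic` and `phylogenetic` (species pairs from the relation matrices).
#' Omitting a relation matrix yields the corresponding ablation graph; with
#' both omitted the graph is bipartite.
#'
#' Species-species edges are stored once per unordered pair; the transformer
#' realises every edge in both directions so each node can aggregate from all
#' its neighbours.
#'
#' @param A Preprocessed species x sample matrix (see
#'   [preprocess_abundance()]).
#' @param D1 Optional binary metabolic relation matrix aligned to `rownames(A)`.
#' @param D2 Optional binary phylogenetic relation matrix, same alignment.
#' @return An object of class `"hetero_graph"`.
#' @export
build_graph <- function(A, D1 = NULL, D2 = NULL) {
  validate_abundance(A)
  species <- rownames(A)
  samples <- colnames(A)
  pairs_from <- function(D, what) {
    if (is.null(D)) return(matrix(integer(), 0L, 2L))
    if (!identical(rownames(D), species))
      stop(what, " relation matrix species do not match the abundance matrix")
    idx <- which(D != 0 & upper.tri(D), arr.ind = TRUE)
    unname(idx)
  }
  e1 <- pairs_from(D1, "metabolic")
  e2 <- pairs_from(D2, "phylogenetic")
  ab <- which(A > 0, arr.ind = TRUE)
  structure(list(
    species_ids = species,
    sample_ids = samples,
    edges_metabolic = e1,       # columns: species i1, species i2 (i1 < i2)
    edges_phylogenetic = e2,
    edges_abundance = cbind(unname(ab), weight = A[ab]),  # species, sample, a_ij
    abundance = A
  ), class = "hetero_graph")
}

#' Summarise a heterogeneous graph
#'
#' @param G A `"hetero_graph"`.
#' @return List with node counts per type, undirected edge counts per type,
#'   species-sample edge density, and the number of isolated nodes.
#' @export
graph_summary <- function(G) {
  stopifnot(inherits(G, "hetero_graph"))
  M <- length(G$species_ids); N <- length(G$sample_ids)
  deg_s <- tabulate(c(G$edges_abundance[, 1L], G$edges_metabolic,
                      G$edges_phylogenetic), nbins = M)
  deg_p <- tabulate(G$edges_abundance[, 2L], nbins = N)
  list(species = M, samples = N,
       abundance_edges = nrow(G$edges_abundance),
       metabolic = nrow(G$edges_metabolic),
       phylogenetic = nrow(G$edges_phylogenetic),
       abundance_density = nrow(G$edges_abundance) / (M * N),
       isolated_nodes = sum(deg_s == 0L) + sum(deg_p == 0L))
}

#' @export
print.hetero_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("Species-sample heterogeneous graph\n")
  cat(sprintf("  nodes: %d species, %d samples\n", s$species, s$samples))
  cat(sprintf("  edges: %d abundance (density %.3f), %d metabolic, %d phylogenetic\n",
              s$abundance_edges, s$abundance_density, s$metabolic, s$phylogenetic))
  if (s$isolated_nodes) cat("  isolated nodes:", s$isolated_nodes, "\n")
  invisible(x)
}

#' Export a graph as edge-list and node tables
#'
#' Writes one TSV per edge type (`src`, `dst`, `weight`) and a node table
#' (`node_id`, `type`) into `dir`.
#'
#' @param G A `"hetero_graph"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_graph <- function(G, dir) {
  stopifnot(inherits(G, "hetero_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(data.frame(node_id = c(G$species_ids, G$sample_ids),
                type = rep(c("species", "sample"),
                           c(length(G$species_ids), length(G$sample_ids)))),
     "nodes.tsv")
  ss <- function(e) data.frame(src = G$species_ids[e[, 1L]],
                               dst = G$species_ids[e[, 2L]],
                               weight = rep(1, nrow(e)))
  wt(ss(G$edges_metabolic), "edges_metabolic.tsv")
  wt(ss(G$edges_phylogenetic), "edges_phylogenetic.tsv")
  wt(data.frame(src = G$species_ids[G$edges_abundance[, 1L]],
                dst = G$sample_ids[G$edges_abundance[, 2L]],
                weight = G$edges_abundance[, 3L]),
     "edges_abundance.tsv")
  invisible(dir)
}
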