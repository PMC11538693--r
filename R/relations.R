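#' Metabolic species-species relation matrix from a compound table
#'
#' Two species are metabolically related when they consume the same compound
#' (competition) or when a compound one species consumes is produced by the
#' other (complementarity). The two relation kinds are merged without
#' distinction into a single binary, symmetric, zero-diagonal matrix. A
#' compound consumed by more than two species links every pair of its
#' consumers (pairwise rule). Species in `species_ids` absent from the table
#' simply receive no edges.
#'
#' @param table Data frame with columns `species_id`, `compound_id`,
#'   `direction` (values `"produce"` / `"consume"`); duplicates are removed.
#' @param species_ids Character vector of species to index the matrix by.
#' @return Binary M x M matrix with `species_ids` dimnames and attribute
#'   `kind = "metabolic"`.
#' @export
metabolic_relations <- function(table, species_ids) {
  stopifnot(length(species_ids) > 0)
  table <- validate_compound_table(table)
  table <- table[table$species_id %in% species_ids, , drop = FALSE]
  M <- length(species_ids)
  D <- matrix(0, M, M, dimnames = list(species_ids, species_ids))
  if (nrow(table)) {
    compounds <- unique(table$compound_id)
    # incidence matrices species x compound
    cons <- matrix(0, M, length(compounds),
                   dimnames = list(species_ids, compounds))
    prod <- cons
    is_cons <- table$direction == "consume"
    cons[cbind(match(table$species_id[is_cons], species_ids),
               match(table$compound_id[is_cons], compounds))] <- 1
    prod[cbind(match(table$species_id[!is_cons], species_ids),
               match(table$compound_id[!is_cons], compounds))] <- 1
    shared <- tcrossprod(cons)                    # competition
    compl <- tcrossprod(prod, cons)               # i produces what j consumes
    D[] <- as.numeric(shared + compl + t(compl) > 0)
    diag(D) <- 0
  }
  attr(D, "kind") <- "metabolic"
  D
}

validate_compound_table <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("species_id", "compound_id", "direction")
  if (!all(need %in% colnames(table)))
    stop("compound table needs columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(table$direction), c("produce", "consume"))
  if (length(bad))
    stop("unknown direction token(s): ", paste(bad, collapse = ", "))
  unique(table[need])
}

#' Phylogenetic species-species relation matrix from a taxonomy table
#'
#' Links two distinct species when they belong to the same genus. Species in
#' `species_ids` with no taxonomy record get no edges (with a warning); a
#' species mapped to more than one genus is an error.
#'
#' @param taxonomy Data frame with columns `species_id`, `genus_id`.
#' @param species_ids Species to index the matrix by.
#' @return Binary M x M matrix, attribute `kind = "phylogenetic"`.
#' @export
phylogenetic_relations <- function(taxonomy, species_ids) {
  stopifnot(length(species_ids) > 0)
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if (!all(c("species_id", "genus_id") %in% colnames(taxonomy)))
    stop("taxonomy table needs columns species_id, genus_id")
  taxonomy <- unique(taxonomy[c("species_id", "genus_id")])
  multi <- unique(taxonomy$species_id[duplicated(taxonomy$species_id)])
  if (length(multi))
    stop("species mapped to more than one genus: ", paste(multi, collapse = ", "))
  genus <- taxonomy$genus_id[match(species_ids, taxonomy$species_id)]
  if (anyNA(genus))
    warning("species without taxonomy record get no phylogenetic edges: ",
            paste(species_ids[is.na(genus)], collapse = ", "))
  M <- length(species_ids)
  D <- matrix(0, M, M, dimnames = list(species_ids, species_ids))
  ok <- !is.na(genus)
  same <- outer(genus[ok], genus[ok], "==")
  D[ok, ok] <- as.numeric(same)
  diag(D) <- 0
  attr(D, "kind") <- "phylogenetic"
  D
}

#' Validate and align a user-supplied relation matrix
#'
#' Symmetrises by logical OR, forces the diagonal to zero (with a warning when
#' it was non-zero), and subsets/reorders rows and columns to `species_ids`.
#' Species missing from the supplied matrix receive all-zero rows/columns.
#'
#' @param D Square 0/1 matrix with identifier dimnames.
#' @param species_ids Target species order.
#' @param kind `"metabolic"` or `"phylogenetic"` (stored as an attribute).
#' @return Binary matrix aligned to `species_ids`.
#' @export
validate_relation_matrix <- function(D, species_ids,
                                     kind = c("metabolic", "phylogenetic")) {
  kind <- match.arg(kind)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("relation matrix must be square")
  if (is.null(rownames(D)) || is.null(colnames(D)))
    stop("relation matrix needs identifier dimnames")
  if (!identical(rownames(D), colnames(D)))
    stop("relation matrix row and column identifiers differ")
  if (!all(D %in% c(0, 1)))
    stop("relation matrix entries must be 0 or 1")
  if (any(diag(D) != 0)) {
    warning("non-zero diagonal in relation matrix forced to 0")
    diag(D) <- 0
  }
  S <- (D + t(D) > 0) * 1                       # OR symmetrisation
  out <- matrix(0, length(species_ids), length(species_ids),
                dimnames = list(species_ids, species_ids))
  common <- intersect(species_ids, rownames(S))
  out[common, common] <- S[common, common]
  diag(out) <- 0
  attr(out, "kind") <- kind
  out
}

#' Read / write a relation matrix TSV
#'
#' Square tables with an identifier header row and column and a 0/1 body.
#'
#' @param path File path.
#' @param species_ids Species order to align to (see
#'   [validate_relation_matrix()]).
#' @param kind Relation kind attribute.
#' @return The aligned binary matrix.
#' @export
read_relation_matrix <- function(path, species_ids,
                                 kind = c("metabolic", "phylogenetic")) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  D <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(D) <- raw[[1L]]
  storage.mode(D) <- "double"
  validate_relation_matrix(D, species_ids, kind)
}

#' @rdname read_relation_matrix
#' @param D Relation matrix to write.
#' @export
write_relation_matrix <- function(D, path) {
  df <- data.frame(species_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
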