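#' Run the full identification pipeline and write its artifacts
#'
#' Orchestrates preprocess, relation-matrix derivation, graph construction,
#' autoencoder initialisation, transformer training, and community inference,
#' writing every artifact (communities, attention, thresholds, loss trace,
#' graph export, resolved configuration) into `out_dir`.
#'
#' @param abundance Species x sample matrix, or path to an abundance TSV.
#' @param labels `"sample_labels"`, named character vector, or path to a
#'   labels TSV.
#' @param metabolic Optional relation matrix, compound table (data frame with
#'   `species_id`, `compound_id`, `direction`), or path to either.
#' @param phylogenetic Optional relation matrix, taxonomy table (data frame
#'   with `species_id`, `genus_id`), or path.
#' @param out_dir Output directory.
#' @param control [hgt_control()] settings.
#' @param z_alpha,cutoff,adjust Community-inference settings (see
#'   [communities()]); `z_alpha = "auto"` calibrates the threshold
#'   multiplier per run.
#' @param min_nonzero_frac Preprocessing filter threshold.
#' @return The `"hgt_fit"` object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(abundance, labels, metabolic = NULL,
                         phylogenetic = NULL, out_dir,
                         control = hgt_control(), z_alpha = "auto",
                         cutoff = 0.05, adjust = "bh",
                         min_nonzero_frac = 5e-4) {
  t0 <- Sys.time()
  log_line <- function(...) message(format(Sys.time(), "%H:%M:%S "),
                                    sprintf(...))
  A <- if (is.character(abundance)) read_abundance(abundance) else abundance
  A <- preprocess_abundance(A, min_nonzero_frac)
  if (is.character(labels)) labels <- read_labels(labels)
  if (!inherits(labels, "sample_labels"))
    labels <- encode_labels(labels, sample_ids = colnames(A))
  log_line("preprocess: %d species x %d samples, %d classes",
           nrow(A), ncol(A), length(labels$classes))

  as_relation <- function(x, kind) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      first <- readLines(x, n = 1L)
      x <- if (grepl("compound_id|genus_id", first))
        utils::read.delim(x, stringsAsFactors = FALSE) else
          read_relation_matrix(x, rownames(A), kind)
    }
    if (is.matrix(x)) return(validate_relation_matrix(x, rownames(A), kind))
    if (kind == "metabolic") metabolic_relations(x, rownames(A))
    else phylogenetic_relations(x, rownames(A))
  }
  D1 <- as_relation(metabolic, "metabolic")
  D2 <- as_relation(phylogenetic, "phylogenetic")

  fit <- hgt_fit(A, labels, D1, D2, control = control, preprocess = FALSE)
  log_line("training done: accuracy %.3f, final loss %.5f",
           fit$accuracy, utils::tail(fit$loss_trace$total, 1))
  comm <- communities(fit, z_alpha = z_alpha, cutoff = cutoff,
                      adjust = adjust)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_communities(comm, out_dir)
  write_attention(fit, file.path(out_dir, "attention.tsv"))
  utils::write.table(fit$loss_trace, file.path(out_dir, "loss_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_graph(fit$graph, file.path(out_dir, "graph"))
  cfg <- c(unclass(control),
           list(z_alpha = z_alpha, cutoff = cutoff, adjust = adjust,
                min_nonzero_frac = min_nonzero_frac,
                n_species = nrow(A), n_samples = ncol(A),
                classes = paste(labels$classes, collapse = ","),
                abundance_sha = unname(sum(A)),  # cheap content fingerprint
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = " "), ""), sep = "\t"),
    file.path(out_dir, "config.tsv"))
  fit$communities <- comm
  invisible(fit)
}

#' Reproducibility experiment over the full pipeline
#'
#' Runs [subsample_experiment()] with the package's own fit-and-infer chain
#' as the plug-in method, over a grid of subsample fractions, and writes the
#' report.
#'
#' @param abundance Species x sample matrix (already preprocessed or raw).
#' @param labels `"sample_labels"` or named character vector.
#' @param r_list Subsample fractions; default `c(0.80, 0.85, 0.90, 0.95)`.
#' @param K Repeats per fraction; default 50.
#' @param control [hgt_control()] for each subsampled fit.
#' @param out_dir Optional directory for the TSV report.
#' @param metabolic,phylogenetic Optional relation matrices (aligned after
#'   preprocessing internally).
#' @param z_alpha,cutoff,adjust Community-inference settings.
#' @param seed Seed for the subsample draws.
#' @return Named list of `"reproducibility_result"`, one per `r`.
#' @export
run_reproducibility <- function(abundance, labels,
                                r_list = c(0.80, 0.85, 0.90, 0.95), K = 50L,
                                control = hgt_control(), out_dir = NULL,
                                metabolic = NULL, phylogenetic = NULL,
                                z_alpha = "auto", cutoff = 0.05, adjust = "bh",
                                seed = 1L) {
  if (any(r_list <= 0 | r_list > 1)) stop("r must be in (0, 1]")
  if (!inherits(labels, "sample_labels"))
    labels <- encode_labels(labels, sample_ids = colnames(abundance))
  method <- function(A_sub, lab_sub, run) {
    ctl <- control
    ctl$seed <- control$seed + run
    fit <- hgt_fit(A_sub, lab_sub,
                   D1 = metabolic, D2 = phylogenetic,
                   control = ctl)
    community_sets(communities(fit, z_alpha = z_alpha, cutoff = cutoff,
                               adjust = adjust))
  }
  out <- lapply(r_list, function(r)
    subsample_experiment(abundance, labels, method, r = r, K = K,
                         seed = seed))
  names(out) <- paste0("r", r_list)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rows <- do.call(rbind, lapply(seq_along(r_list), function(i) {
      res <- out[[i]]
      rbind(data.frame(r = r_list[i], K = K, class = names(res$RJ_c),
                       RJ_c = unname(res$RJ_c)),
            data.frame(r = r_list[i], K = K, class = "RJ", RJ_c = res$RJ))
    }))
    utils::write.table(rows, file.path(out_dir, "reproducibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
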