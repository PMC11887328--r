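#' Run the full alignment-free phylogeny pipeline
#'
#' Orchestrates the four stages: (1) enumerate per-taxon k-mer sets for
#' every odd k in `[k_min, k_max]`, (2) assemble the presence/absence
#' matrix per k (cached on disk, since matrix construction dominates
#' runtime), (3) pick `k_entropy` by maximum cumulative entropy, skipping
#' degenerate k values, and (4) estimate the ML tree on the selected
#' matrix, optionally with bootstrap supports.
#'
#' @param input Named list of contig vectors (see [read_fasta()]), a
#'   directory of FASTA files, a manifest TSV path, or a character vector
#'   of FASTA paths.
#' @param out_dir Output directory; created if missing. Artifacts:
#'   `entropy.tsv`, `matrix_k<k>.phy` (selected k), `tree.nwk`,
#'   `consensus.nwk` (if bootstrapped), `report.json`, `run.log` and
#'   `cache/` with per-k PHYLIP matrices.
#' @param mode `"canonical"` (default) or `"non-canonical"` k-mer
#'   counting.
#' @param k_min,k_max Odd bounds of the k grid (defaults 9 and 31).
#' @param q Rows sampled for the entropy score (default 5000).
#' @param seed Seed for entropy sampling and bootstrap (default 42).
#' @param bootstrap Number of bootstrap replicates (default 0 = off).
#' @param ncat Gamma rate categories (default 4).
#' @param tree_mode If `FALSE`, stop after the entropy profile (allows
#'   2-3 taxa).
#' @param cache Reuse per-k matrices cached in `out_dir/cache` (default
#'   `TRUE`).
#' @return Invisibly, a list with the entropy `profile`, `k_entropy`, the
#'   selected `matrix`, the [binml()] `fit`, the final `tree`, bootstrap
#'   results and the paths of all written artifacts.
#' @export
run_pipeline <- function(input, out_dir, mode = c("canonical", "non-canonical"),
                         k_min = 9, k_max = 31, q = 5000, seed = 42,
                         bootstrap = 0, ncat = 4, tree_mode = TRUE,
                         cache = TRUE) {
  mode <- match.arg(mode)
  if (k_min %% 2 == 0 || k_max %% 2 == 0 || k_min > k_max)
    stop("k_min and k_max must be odd with k_min <= k_max")
  records <- resolve_input(input)
  m <- length(records)
  if (tree_mode && m < 4) stop("need >= 4 taxa for tree estimation")
  if (m < 2) stop("need >= 2 taxa")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  if (cache) dir.create(cache_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pipeline: mode=%s k=%d..%d (odd) q=%d seed=%d bootstrap=%d ncat=%d",
       mode, k_min, k_max, q, seed, bootstrap, ncat)
  logf("taxa (%d): %s", m, paste(names(records), collapse = ", "))

  ks <- seq(k_min, k_max, by = 2)
  matrices <- list()
  for (k in ks) {
    cache_file <- file.path(cache_dir, sprintf("matrix_k%02d_%s.phy", k, mode))
    x <- NULL
    if (cache && file.exists(cache_file)) {
      tx <- read_phylip(cache_file)
      x <- t(tx)
      logf("k=%d: matrix read from cache (%d k-mers)", k, nrow(x))
    } else {
      x <- try(kmer_matrix(records, k = k, mode = mode), silent = TRUE)
      if (inherits(x, "try-error")) {
        logf("k=%d: matrix build failed: %s", k, attr(x, "condition")$message)
      } else {
        if (cache) export_phylip(x, cache_file)
        logf("k=%d: %d k-mers x %d taxa", k, nrow(x), ncol(x))
      }
    }
    matrices[[as.character(k)]] <- x
  }

  profile <- entropy_profile(matrices, q = q, seed = seed)
  k_entropy <- attr(profile, "k_entropy")
  for (i in seq_len(nrow(profile)))
    logf("k=%d: C_entropy=%s q_used=%s status=%s", profile$k[i],
         format(profile$entropy[i]), format(profile$q_used[i]),
         profile$status[i])
  logf("selected k_entropy=%d (argmax cumulative entropy, ties -> smallest k)",
       k_entropy)
  entropy_path <- file.path(out_dir, "entropy.tsv")
  write_entropy_tsv(profile, entropy_path)

  x_sel <- matrices[[as.character(k_entropy)]]
  phylip_path <- file.path(out_dir, sprintf("matrix_k%d.phy", k_entropy))
  export_phylip(x_sel, phylip_path)

  result <- list(profile = profile, k_entropy = k_entropy, matrix = x_sel,
                 paths = list(entropy = entropy_path, matrix = phylip_path,
                              log = log_path))
  if (!tree_mode) {
    report_path <- file.path(out_dir, "report.json")
    write_report(report_path, mode, k_min, k_max, q, seed, bootstrap, ncat,
                 profile, k_entropy, fit = NULL)
    result$paths$report <- report_path
    return(invisible(result))
  }

  fit <- binml(x_sel, ncat = ncat)
  logf("ML fit: logL=%.4f alpha=%.4g pi1=%.4f; logL trajectory: %s",
       fit$logLik, fit$model$alpha, fit$model$pi[2],
       paste(sprintf("%.4f", fit$trajectory), collapse = " -> "))
  tree_out <- fit$tree
  boot <- NULL
  if (bootstrap > 0) {
    btrees <- bootstrap_trees(x_sel, B = bootstrap, seed = seed, ncat = ncat)
    boot <- majority_consensus(btrees, besttree = fit$tree)
    tree_out <- boot$annotated
    cons_path <- file.path(out_dir, "consensus.nwk")
    ape::write.tree(boot$consensus, cons_path)
    result$paths$consensus <- cons_path
    logf("bootstrap: B=%d, consensus written", bootstrap)
  }
  tree_path <- file.path(out_dir, "tree.nwk")
  ape::write.tree(tree_out, tree_path)
  report_path <- file.path(out_dir, "report.json")
  write_report(report_path, mode, k_min, k_max, q, seed, bootstrap, ncat,
               profile, k_entropy, fit)
  result$fit <- fit
  result$tree <- tree_out
  result$bootstrap <- boot
  result$paths$tree <- tree_path
  result$paths$report <- report_path
  invisible(result)
}

resolve_input <- function(input) {
  if (is.list(input)) return(input)
  if (length(input) == 1 && dir.exists(input)) {
    paths <- sort(list.files(input, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0) stop("no FASTA files in ", input)
    return(read_fasta(paths))
  }
  read_fasta(input)
}

write_report <- function(path, mode, k_min, k_max, q, seed, bootstrap, ncat,
                         profile, k_entropy, fit) {
  report <- list(
    package = "kmerphylo",
    version = as.character(utils::packageVersion("kmerphylo")),
    config = list(mode = mode, k_min = k_min, k_max = k_max, q = q,
                  seed = seed, bootstrap = bootstrap, ncat = ncat),
    k_entropy = k_entropy,
    entropy = stats::setNames(as.list(profile$entropy),
                              as.character(profile$k)),
    skipped_k = profile$k[profile$status != "ok"])
  if (!is.null(fit)) {
    report$logLik <- fit$logLik
    report$alpha <- unname(fit$model$alpha)
    report$pi <- as.list(fit$model$pi)
    report$tree <- write_newick(fit$tree)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
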