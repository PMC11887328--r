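#' Shannon entropy of binary matrix rows
#'
#' For a 0/1 row observed across m taxa, the entropy of the empirical state
#' distribution is `-sum(p(x) log p(x))` over x in {0, 1}, with
#' `p(x) = count(x) / m` and the convention `0 log 0 = 0`. Constant rows
#' (k-mers present in all taxa, or in just one of many) carry little
#' phylogenetic information and score near zero; balanced rows score up to
#' `log 2` nats.
#'
#' @param x A 0/1 vector, or a 0/1 matrix whose rows are scored at once.
#' @return Numeric entropy value(s) in nats, in `[0, log(2)]`.
#' @examples
#' row_entropy(c(1, 0))       # log(2)
#' row_entropy(rep(1, 10))    # 0
#' @export
row_entropy <- function(x) {
  if (is.matrix(x)) {
    if (!all(x == 0L | x == 1L)) stop("entries must be 0 or 1")
    p <- rowMeans(x)
  } else {
    if (!all(x == 0L | x == 1L)) stop("entries must be 0 or 1")
    p <- mean(x)
  }
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  -(xlogx(p) + xlogx(1 - p))
}

#' Cumulative entropy of a presence/absence matrix
#'
#' Sums [row_entropy()] over `q` rows sampled uniformly without replacement
#' (a seeded shuffle prefix, so enlarging `q` under the same seed only adds
#' rows). When the matrix has at most `q` rows all rows are used and the
#' result is seed-independent. This is the information score used to choose
#' between k-mer lengths.
#'
#' @param x Presence/absence matrix from [build_matrix()].
#' @param q Number of rows to sample (default 5000).
#' @param seed Sampling seed (default 42).
#' @return Numeric scalar, the cumulative entropy in nats, with attribute
#'   `q_used` giving the number of rows actually summed.
#' @export
cumulative_entropy <- function(x, q = 5000, seed = 42) {
  stopifnot(is.matrix(x), q >= 1)
  n <- nrow(x)
  if (n == 0) stop("empty matrix")
  if (n <= q) {
    idx <- seq_len(n)
  } else {
    idx <- with_seed(seed, sample.int(n))[seq_len(q)]
  }
  out <- sum(row_entropy(x[idx, , drop = FALSE]))
  attr(out, "q_used") <- length(idx)
  out
}

#' Entropy profile across k-mer lengths
#'
#' Computes the cumulative entropy of each per-k matrix and selects
#' `k_entropy`, the k maximizing it (ties broken toward the smallest k).
#' Degenerate k values — an all-ones matrix (zero entropy by construction,
#' uninformative) or a matrix that failed to build — are skipped and
#' recorded rather than aborting the run.
#'
#' @param matrices Named list mapping k (as names) to presence/absence
#'   matrices; entries may be `NULL` or a `try-error` for failed builds.
#' @param q,seed Passed to [cumulative_entropy()]; sampling is seeded
#'   independently for each k.
#' @return An object of class `entropy_profile`: a data frame with columns
#'   `k`, `entropy`, `q_used`, `status`, plus attributes `k_entropy` and
#'   `seed`.
#' @export
entropy_profile <- function(matrices, q = 5000, seed = 42) {
  ks <- as.integer(names(matrices))
  if (any(is.na(ks))) stop("matrices must be named by integer k")
  res <- data.frame(k = ks, entropy = NA_real_, q_used = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(ks)) {
    x <- matrices[[i]]
    if (is.null(x) || inherits(x, "try-error")) {
      res$status[i] <- "build-failed"
      next
    }
    if (all(x == 1L)) {
      res$status[i] <- "degenerate-all-ones"
      res$entropy[i] <- 0
      res$q_used[i] <- 0L
      next
    }
    ce <- cumulative_entropy(x, q = q, seed = seed)
    res$entropy[i] <- as.numeric(ce)
    res$q_used[i] <- attr(ce, "q_used")
  }
  res <- res[order(res$k), , drop = FALSE]
  usable <- res$status == "ok"
  if (!any(usable)) {
    stop("no usable k: ",
         paste(sprintf("k=%d (%s)", res$k[!usable], res$status[!usable]),
               collapse = ", "))
  }
  best <- which(usable)[which.max(res$entropy[usable])]
  # which.max already returns the first (smallest-k) maximum among usable ks
  attr(res, "k_entropy") <- res$k[best]
  attr(res, "seed") <- seed
  class(res) <- c("entropy_profile", "data.frame")
  res
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("Entropy profile over k-mer lengths\n")
  print.data.frame(x, row.names = FALSE)
  cat("selected k_entropy =", attr(x, "k_entropy"), "\n")
  invisible(x)
}

#' Write an entropy profile as TSV
#'
#' @param profile An [entropy_profile()] result.
#' @param path Output TSV path (columns k, C_entropy, q_used, status).
#' @return `path`, invisibly.
#' @export
write_entropy_tsv <- function(profile, path) {
  df <- data.frame(k = profile$k, C_entropy = profile$entropy,
                   q_used = profile$q_used, status = profile$status)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
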