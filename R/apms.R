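# AP-MS quantitative front end: bait-prey peptide counts -> abundance
# ratios -> connectivity matrix via a logistic map.

#' Peptide-count table
#'
#' @param counts data frame with columns `bait`, `prey`, `count`
#'   (non-negative integers)
#' @param lengths named numeric vector of protein sequence lengths
#'   (residues); every referenced protein must have one
#' @return object of class `peptide_table`
#' @export
peptide_table <- function(counts, lengths) {
  counts <- data.frame(bait = as.character(counts[[1]]),
                       prey = as.character(counts[[2]]),
                       count = as.numeric(counts[[3]]))
  if (any(counts$count < 0)) stop("peptide counts must be non-negative")
  prots <- unique(c(counts$bait, counts$prey))
  missing <- setdiff(prots, names(lengths))
  if (length(missing) > 0) {
    stop("missing protein lengths for: ", paste(missing, collapse = ", "))
  }
  if (any(lengths[prots] <= 0)) stop("protein lengths must be positive")
  structure(list(counts = counts, lengths = lengths), class = "peptide_table")
}

#' Read / write a peptide-count table
#'
#' `counts_path` is a TSV with columns bait, prey, count; `lengths_path` a
#' TSV with columns protein, length.
#'
#' @param counts_path,lengths_path file paths
#' @return a [peptide_table()]
#' @export
read_peptide_counts <- function(counts_path, lengths_path) {
  cts <- read.table(counts_path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"))
  lens <- read.table(lengths_path, sep = "\t", header = TRUE,
                     colClasses = c("character", "numeric"))
  peptide_table(cts, setNames(lens[[2]], lens[[1]]))
}

#' @rdname read_peptide_counts
#' @param table a `peptide_table`
#' @export
write_peptide_counts <- function(table, counts_path, lengths_path) {
  write.table(table$counts, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(protein = names(table$lengths),
                         length = unname(table$lengths)),
              lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Normalize peptide counts to abundance ratios
#'
#' Peptide counts are biased towards long proteins, so each bait->prey count
#' is divided by the prey's sequence length: `R(i,j) = count(i->j) /
#' length(j)`. Unobserved entries stay `NA` (absent), to be distinguished
#' from an observed zero.
#'
#' @param table a [peptide_table()]
#' @return square numeric matrix of ratios with `NA` for unobserved pairs
#' @export
normalize_counts <- function(table) {
  prots <- sort(unique(c(table$counts$bait, table$counts$prey)))
  R <- matrix(NA_real_, length(prots), length(prots),
              dimnames = list(prots, prots))
  R[cbind(table$counts$bait, table$counts$prey)] <-
    table$counts$count / table$lengths[table$counts$prey]
  R
}

#' Logistic parameters
#'
#' Defaults to the parameters fitted against the simulated connectivity
#' distribution of a gold-standard yeast binary-interaction network.
#'
#' @param alpha location
#' @param beta scale (sign free, non-zero); note that a negative `beta`
#'   makes the transform decreasing in the abundance ratio
#' @return a `logistic_params` list
#' @export
logistic_params <- function(alpha = 2.8921, beta = -0.6318) {
  if (beta == 0) stop("beta must be non-zero")
  structure(list(alpha = alpha, beta = beta), class = "logistic_params")
}

#' Map abundance ratios to a connectivity matrix
#'
#' Symmetrizes the ratio matrix (averaging the two directions where both
#' were observed) and applies `M(i,j) = 1 / (1 + exp(-(R(i,j) - alpha) /
#' beta))`. Pairs never observed map to connectivity 0 — an unobserved pair
#' carries no evidence of connection — and the diagonal is 1.
#'
#' @param R ratio matrix from [normalize_counts()]
#' @param params a [logistic_params()]
#' @param p_hat survival probability recorded on the output matrix
#' @return a [connectivity_matrix()]
#' @export
logistic_transform <- function(R, params = logistic_params(), p_hat = 0.5) {
  Rsym <- R
  both <- !is.na(R) & !is.na(t(R))
  Rsym[both] <- (R[both] + t(R)[both])
  Rsym[both] <- Rsym[both] / 2
  one <- is.na(R) & !is.na(t(R))
  Rsym[one] <- t(R)[one]
  M <- 1 / (1 + exp(-(Rsym - params$alpha) / params$beta))
  M[is.na(Rsym)] <- 0
  M <- pmin(pmax(M, 0), 1)
  diag(M) <- 1
  connectivity_matrix((M + t(M)) / 2, p_hat = p_hat, delta = 0, n_samples = 0)
}

#' Fit logistic parameters against a reference connectivity distribution
#'
#' Chooses `(alpha, beta)` so the histogram of transformed ratios matches
#' the reference histogram of connectivity values, minimizing the chi-square
#' distance over shared bins (coarse grid search followed by Nelder-Mead
#' refinement).
#'
#' @param R ratio matrix (off-diagonal observed entries are used)
#' @param reference numeric vector of reference connectivity values in
#'   `[0,1]`
#' @param bins number of equal-width histogram bins on `[0,1]` (default 20)
#' @return fitted [logistic_params()]
#' @export
fit_logistic_params <- function(R, reference, bins = 20) {
  x <- R[upper.tri(R) | lower.tri(R)]
  x <- x[!is.na(x)]
  breaks <- seq(0, 1, length.out = bins + 1)
  ref_h <- tabulate(pmin(findInterval(reference, breaks,
                                      rightmost.closed = TRUE), bins),
                    nbins = bins)
  if (sum(ref_h > 0) < 2) stop("reference distribution is degenerate (single bin)")
  ref_h <- ref_h / sum(ref_h)
  chisq <- function(par) {
    m <- 1 / (1 + exp(-(x - par[1]) / par[2]))
    h <- tabulate(pmin(findInterval(m, breaks, rightmost.closed = TRUE), bins),
                  nbins = bins)
    h <- h / sum(h)
    sum((h - ref_h)^2 / (ref_h + 1e-9))
  }
  grid <- expand.grid(alpha = seq(min(x), max(x) + 1e-6, length.out = 25),
                      beta = c(seq(-3, -0.05, length.out = 15),
                               seq(0.05, 3, length.out = 15)))
  vals <- apply(grid, 1, chisq)
  # the histogram distance is plateau-ridden; refine from several starts
  starts <- grid[order(vals)[1:5], ]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- optim(as.numeric(starts[k, ]), chisq, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  logistic_params(alpha = best$par[1], beta = best$par[2])
}
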