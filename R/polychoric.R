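#' Two-step polychoric correlation
#'
#' Estimates the correlation of the latent bivariate-normal variables
#' assumed to underlie two observed ordinal variables.  Step one fixes the
#' thresholds at inverse-normal transforms of the cumulative marginal
#' proportions; step two maximizes the bivariate-normal cell likelihood
#' over the correlation in (-0.999, 0.999).
#'
#' @param x,y Ordinal vectors (factors or integers) of equal length;
#'   pairwise-complete observations are used.
#' @return A list: `rho` (the estimate), `thresholds_x`, `thresholds_y`,
#'   `loglik`, `boundary` (TRUE when the estimate hits the search bound,
#'   as with perfectly associated variables), `n`.
#' @export
polychoric_correlation <- function(x, y) {
  xy <- prepare_ordinal_pair(x, y)
  tab <- table(xy$x, xy$y)
  tx <- ordinal_thresholds(rowSums(tab))
  ty <- ordinal_thresholds(colSums(tab))

  nll <- function(r) {
    pr <- bivariate_cell_probs(tx, ty, r)
    -sum(tab * log(pmax(pr, 1e-12)))
  }
  opt <- stats::optimize(nll, interval = c(-0.999, 0.999))
  boundary <- abs(opt$minimum) > 0.995
  list(rho = opt$minimum, thresholds_x = tx, thresholds_y = ty,
       loglik = -opt$objective, boundary = boundary, n = sum(tab))
}

prepare_ordinal_pair <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must share length")
  to_int <- function(v) {
    if (is.factor(v)) as.integer(v) else as.integer(v)
  }
  xi <- to_int(x); yi <- to_int(y)
  keep <- !is.na(xi) & !is.na(yi)
  xi <- xi[keep]; yi <- yi[keep]
  if (length(unique(xi)) < 2 || length(unique(yi)) < 2) {
    rlang::abort("polychoric correlation is undefined for a variable with one observed category",
                 class = "latuse_undefined_correlation")
  }
  list(x = xi, y = yi)
}

ordinal_thresholds <- function(counts) {
  cum <- cumsum(counts) / sum(counts)
  stats::qnorm(cum[-length(cum)])
}

bivariate_cell_probs <- function(tx, ty, r) {
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  corr <- matrix(c(1, r, r, 1), 2)
  cdf <- matrix(0, length(ax), length(ay))
  for (i in seq_along(ax)) {
    for (j in seq_along(ay)) {
      cdf[i, j] <- if (is.infinite(ax[i]) && ax[i] < 0 ||
                       is.infinite(ay[j]) && ay[j] < 0) 0
      else if (is.infinite(ax[i]) && is.infinite(ay[j])) 1
      else if (is.infinite(ax[i])) stats::pnorm(ay[j])
      else if (is.infinite(ay[j])) stats::pnorm(ax[i])
      else mvtnorm::pmvnorm(upper = c(ax[i], ay[j]), corr = corr)[1]
    }
  }
  nr <- length(ax) - 1L; nc <- length(ay) - 1L
  pr <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      pr[i, j] <- cdf[i + 1, j + 1] - cdf[i, j + 1] - cdf[i + 1, j] + cdf[i, j]
    }
  }
  pr
}

#' @rdname polychoric_correlation
#' @param data A data frame of ordinal columns.
#' @param columns Column names; defaults to every codebook indicator
#'   present.
#' @param codebook Codebook supplying the category order.
#' @return `polychoric_matrix()`: a symmetric correlation matrix.
#' @export
polychoric_matrix <- function(data, columns = NULL,
                              codebook = default_codebook()) {
  if (is.null(columns)) {
    columns <- intersect(codebook$indicators$id, names(data))
  }
  m <- diag(1, length(columns))
  dimnames(m) <- list(columns, columns)
  for (i in seq_along(columns)) {
    for (j in seq_len(i - 1L)) {
      xi <- factor(as.character(data[[columns[i]]]), levels = codebook$categories)
      xj <- factor(as.character(data[[columns[j]]]), levels = codebook$categories)
      m[i, j] <- m[j, i] <- polychoric_correlation(xi, xj)$rho
    }
  }
  m
}
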