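# shared fixtures and oracles, built in code at test time

# a deterministic 3-row survey covering every response category
fixture_survey <- function() {
  cb <- default_codebook()
  ids <- cb$indicators$id
  base <- tibble::tibble(
    individual_id = c("i1", "i2", "i3"),
    household_id = c("h1", "h1", "h2"))
  for (j in seq_along(ids)) {
    base[[ids[j]]] <- c("agree", "disagree", "dont_know")
  }
  base$age <- c(25, 40, 13)
  base$sex <- c("female", "male", "female")
  base$ethnicity <- c("afro_ecuadorian", "chachi", "mestizo_other")
  base$education <- c("primary", NA, "secondary")
  base$payment_type <- c("solely_cash", "not_paid", "not_employed")
  base$cement_walls <- c("yes", "no", NA)
  base$asset_deprived <- c("yes", "no", "yes")
  base$sanitation <- c("basic", "shared", NA)
  base
}

# minimal lca_fit-shaped object for methods that only need estimates
fake_fit <- function(pi, rho, se_rho = NULL, indicators = dimnames(rho)[[1]],
                     categories = dimnames(rho)[[3]]) {
  boundary <- if (is.null(se_rho)) NULL else rho <= 1e-6 | rho >= 1 - 1e-6
  structure(list(pi = pi, rho = rho, se_rho = se_rho, boundary = boundary,
                 indicators = indicators, categories = categories,
                 k = length(pi), converged = TRUE),
            class = "lca_fit")
}

# independent oracle for tiny two-class, two-binary-item instances:
# exhaustive grid over (pi1, rho) — a coarse global sweep followed by a
# 0.01-step local refinement around the coarse optimum
grid_loglik_max <- function(y, coarse = 0.05, fine = 0.01) {
  stopifnot(ncol(y) == 2, all(y %in% 1:2))
  counts <- table(factor(y[, 1], levels = 1:2), factor(y[, 2], levels = 1:2))
  n_pat <- as.numeric(counts)  # cells (1,1),(2,1),(1,2),(2,2)
  pat <- expand.grid(y1 = 1:2, y2 = 1:2)

  eval_grid <- function(p1s, r11s, r12s, r21s, r22s) {
    g <- expand.grid(r11 = r11s, r12 = r12s, r21 = r21s, r22 = r22s)
    best <- -Inf
    best_par <- NULL
    for (p1 in p1s) {
      ll <- rep(0, nrow(g))
      for (q in seq_len(nrow(pat))) {
        a <- ifelse(pat$y1[q] == 1, g$r11, 1 - g$r11) *
          ifelse(pat$y2[q] == 1, g$r12, 1 - g$r12)
        b <- ifelse(pat$y1[q] == 1, g$r21, 1 - g$r21) *
          ifelse(pat$y2[q] == 1, g$r22, 1 - g$r22)
        ll <- ll + n_pat[q] * log(pmax(p1 * a + (1 - p1) * b, 1e-300))
      }
      i <- which.max(ll)
      if (ll[i] > best) {
        best <- ll[i]
        best_par <- c(p1, g$r11[i], g$r12[i], g$r21[i], g$r22[i])
      }
    }
    list(loglik = best, par = best_par)
  }

  s1 <- seq(coarse, 1 - coarse, by = coarse)
  stage1 <- eval_grid(s1, s1, s1, s1, s1)
  around <- function(x) {
    s <- seq(max(x - coarse, fine), min(x + coarse, 1 - fine), by = fine)
    unique(round(s, 10))
  }
  p <- stage1$par
  stage2 <- eval_grid(around(p[1]), around(p[2]), around(p[3]),
                      around(p[4]), around(p[5]))
  max(stage1$loglik, stage2$loglik)
}

# a binary-indicator tibble (agree/disagree) from an integer matrix
binary_indicator_tibble <- function(y) {
  cats <- c("agree", "disagree", "dont_know")
  tibble::tibble(
    item_a = factor(c("agree", "disagree")[y[, 1]], levels = cats),
    item_b = factor(c("agree", "disagree")[y[, 2]], levels = cats))
}
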