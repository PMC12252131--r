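# Phenotypic variance decomposition: fixed-effects ANOVA, Finlay-Wilkinson
# joint regression, and the GGE SVD of environment-centered cell means.

ANOVA_STRATA <- c("Genotype", "ENVs", "Rep", "Genotype:ENVs", "Residuals")

#' Fixed-effects ANOVA of a multi-environment trial
#'
#' Sequential (type I) sums of squares in the fixed order Genotype, ENVs,
#' Rep, Genotype:ENVs, Residuals, with Rep as a crossed main effect. In the
#' balanced case these equal the classical main-effect/interaction sums of
#' squares and are exactly additive; unbalanced input is accepted with a
#' warning (sums of squares then depend on the stated order). The variance
#' share of a stratum is its percentage of the total sum of squares.
#'
#' @param phenotypes data.frame with `genotype_id`, `env_id`, `rep`, and a
#'   numeric column per trait.
#' @param trait trait column to decompose.
#' @return data.frame of class `anova_gxe` with columns `stratum`, `Df`,
#'   `SS`, `MS`, `F`, `p`, `variance_pct`.
#' @export
anova_decompose <- function(phenotypes, trait) {
  if (!trait %in% names(phenotypes)) stop("no trait column '", trait, "'")
  d <- data.frame(G = factor(phenotypes$genotype_id),
                  E = factor(phenotypes$env_id),
                  R = factor(phenotypes$rep),
                  y = phenotypes[[trait]])
  if (nlevels(d$G) < 2 || nlevels(d$E) < 2) {
    stop("need at least 2 genotypes and 2 environments")
  }
  if (nlevels(d$R) < 2) stop("degenerate design: Rep stratum has zero Df")
  cell_n <- table(d$G, d$E, d$R)
  if (length(unique(c(cell_n))) != 1) {
    warning("unbalanced data: sequential sums of squares in the order ",
            "Genotype, ENVs, Rep, Genotype:ENVs")
  }
  if (var(d$y) == 0) {
    # no variation at all: every stratum SS is exactly zero
    df <- c(nlevels(d$G) - 1L, nlevels(d$E) - 1L, nlevels(d$R) - 1L,
            (nlevels(d$G) - 1L) * (nlevels(d$E) - 1L))
    df <- c(df, nrow(d) - 1L - sum(df))
    return(anova_table_from_ss(rep(0, 5), df))
  }
  fit <- lm(y ~ G + E + R + G:E, data = d)
  a <- anova(fit)
  ss <- c(a["G", "Sum Sq"], a["E", "Sum Sq"], a["R", "Sum Sq"],
          a["G:E", "Sum Sq"], a["Residuals", "Sum Sq"])
  df <- c(a["G", "Df"], a["E", "Df"], a["R", "Df"],
          a["G:E", "Df"], a["Residuals", "Df"])
  anova_table_from_ss(ss, df)
}

#' ANOVA table arithmetic from sums of squares
#'
#' Assembles the full table (mean squares, F against the residual mean
#' square, p from the F distribution, variance share as percentage of the
#' total SS) from stratum sums of squares and degrees of freedom. Useful
#' for recomputing published tables where only SS and Df are printed.
#'
#' @param ss,df numeric vectors for the strata, residual stratum last.
#' @param strata stratum labels.
#' @return data.frame of class `anova_gxe`.
#' @export
anova_table_from_ss <- function(ss, df, strata = ANOVA_STRATA) {
  stopifnot(length(ss) == length(df), length(ss) == length(strata))
  n <- length(ss)
  total <- sum(ss)
  ms <- ss / df
  f <- c(ms[-n] / ms[n], NA)
  p <- c(pf(f[-n], df[-n], df[n], lower.tail = FALSE), NA)
  if (total <= 0) {
    warning("no variation: all sums of squares are zero; ",
            "variance percentages set to 0")
    pct <- rep(0, n)
    f[] <- NA; p[] <- NA
  } else {
    pct <- 100 * ss / total
  }
  structure(data.frame(stratum = strata, Df = df, SS = ss, MS = ms,
                       F = f, p = p, variance_pct = pct,
                       stringsAsFactors = FALSE),
            class = c("anova_gxe", "data.frame"))
}

#' @export
print.anova_gxe <- function(x, digits = 4, ...) {
  cat("Multi-environment trial ANOVA (sequential SS)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Finlay-Wilkinson joint regression
#'
#' Environment effects are `E_j = (environment mean) - (grand mean)` of the
#' genotype-by-environment cell means, so they sum to zero. Each genotype's
#' cell means are regressed on `E_j` by ordinary least squares; the slope
#' (conventionally written `1 + b_i`) measures phenotypic plasticity and
#' averages 1 over genotypes on complete data.
#'
#' @param phenotypes data.frame with `genotype_id`, `env_id` and the trait.
#' @param trait trait column.
#' @return data.frame of class `fw_fit` with columns `genotype_id`,
#'   `intercept`, `slope`, `r2`; environment effects in
#'   `attr(, "env_effects")`.
#' @export
fw_regression <- function(phenotypes, trait) {
  if (!trait %in% names(phenotypes)) stop("no trait column '", trait, "'")
  cm <- cell_mean_matrix(phenotypes, trait, require_complete = FALSE)
  n_env_obs <- rowSums(!is.na(cm))
  drop <- n_env_obs < 3
  if (any(drop)) {
    warning(sum(drop), " genotype(s) observed in fewer than 3 ",
            "environments excluded from the joint regression")
    cm <- cm[!drop, , drop = FALSE]
  }
  env_mean <- colMeans(cm, na.rm = TRUE)
  E <- env_mean - mean(env_mean)
  fits <- t(apply(cm, 1, function(y) {
    ok <- !is.na(y)
    f <- lm.fit(cbind(1, E[ok]), y[ok])
    res <- f$residuals
    tss <- sum((y[ok] - mean(y[ok]))^2)
    c(f$coefficients, if (tss > 0) 1 - sum(res^2) / tss else NA_real_)
  }))
  out <- data.frame(genotype_id = rownames(cm), intercept = fits[, 1],
                    slope = fits[, 2], r2 = fits[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("fw_fit", "data.frame"), env_effects = E,
            trait = trait)
}

#' @export
print.fw_fit <- function(x, ...) {
  cat(sprintf("Finlay-Wilkinson joint regression: %s, %d genotypes, %d environments\n",
              attr(x, "trait"), nrow(x), length(attr(x, "env_effects"))))
  cat(sprintf("slope: mean %.3f, range [%.3f, %.3f]; median r2 %.3f\n",
              mean(x$slope), min(x$slope), max(x$slope),
              stats::median(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.fw_fit <- function(object, ...) {
  setNames(object$slope, object$genotype_id)
}

#' @export
plot.fw_fit <- function(x, ...) {
  graphics::hist(x$slope, breaks = 30, col = "grey80",
                 main = paste("FW plasticity slopes:", attr(x, "trait")),
                 xlab = "slope (1 + b)")
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}

# Internal: genotype x environment cell-mean matrix.
cell_mean_matrix <- function(phenotypes, trait, require_complete = TRUE) {
  g <- factor(phenotypes$genotype_id)
  e <- factor(phenotypes$env_id)
  cm <- tapply(phenotypes[[trait]], list(g, e), mean)
  if (require_complete && anyNA(cm)) {
    stop("incomplete genotype x environment mean table; impute or drop ",
         "missing cells upstream")
  }
  cm
}

#' GGE decomposition of environment-centered cell means
#'
#' Models the cell means as `Y_ij = mu + beta_j + sum_k lambda_k *
#' gamma_ik * delta_jk`: each environment's column is centered (removing
#' `mu + beta_j`) and the residual genotype-plus-interaction matrix is
#' factored by singular value decomposition. Axis k explains
#' `lambda_k^2 / sum(lambda^2)` of the GGE variation. Scores use the
#' symmetric scaling, absorbing `sqrt(lambda_k)` into each side.
#'
#' @param phenotypes data.frame with `genotype_id`, `env_id` and the trait.
#' @param trait trait column.
#' @param n_axes number of axes to return scores for (default 2).
#' @return list of class `gge`: `mu`, `beta` (environment main effects),
#'   `singular_values`, `explained_fraction` (all axes),
#'   `genotype_scores`, `env_scores` (first `n_axes`).
#' @export
gge_biplot <- function(phenotypes, trait, n_axes = 2) {
  cm <- cell_mean_matrix(phenotypes, trait, require_complete = TRUE)
  mu <- mean(cm)
  env_mean <- colMeans(cm)
  centered <- sweep(cm, 2, env_mean)
  s <- svd(centered)
  lam2 <- s$d^2
  expl <- if (sum(lam2) > 0) lam2 / sum(lam2) else rep(0, length(lam2))
  n_axes <- min(n_axes, length(s$d))
  k <- seq_len(n_axes)
  gs <- s$u[, k, drop = FALSE] %*% diag(sqrt(s$d[k]), n_axes)
  es <- s$v[, k, drop = FALSE] %*% diag(sqrt(s$d[k]), n_axes)
  dimnames(gs) <- list(rownames(cm), paste0("Axis", k))
  dimnames(es) <- list(colnames(cm), paste0("Axis", k))
  structure(list(mu = mu, beta = env_mean - mu, singular_values = s$d,
                 explained_fraction = expl, genotype_scores = gs,
                 env_scores = es, trait = trait),
            class = "gge")
}

#' @export
print.gge <- function(x, ...) {
  k <- ncol(x$genotype_scores)
  cat(sprintf("GGE decomposition: %s, %d genotypes x %d environments\n",
              x$trait, nrow(x$genotype_scores), nrow(x$env_scores)))
  cat(sprintf("axes 1..%d explain %s of GGE variation\n", k,
              paste(sprintf("%.1f%%", 100 * x$explained_fraction[1:k]),
                    collapse = " + ")))
  invisible(x)
}

#' @export
plot.gge <- function(x, ...) {
  g <- x$genotype_scores; e <- x$env_scores
  lim <- range(c(g[, 1:2], e[, 1:2]))
  plot(g[, 1], g[, 2], pch = 20, col = "grey60", xlim = lim, ylim = lim,
       xlab = sprintf("Axis 1 (%.1f%%)", 100 * x$explained_fraction[1]),
       ylab = sprintf("Axis 2 (%.1f%%)", 100 * x$explained_fraction[2]),
       main = paste("GGE biplot:", x$trait), ...)
  graphics::points(e[, 1], e[, 2], pch = 17, col = "red3")
  graphics::text(e[, 1], e[, 2], rownames(e), pos = 3, col = "red3",
                 cex = 0.7)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
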