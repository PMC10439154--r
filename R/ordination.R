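#' Bray-Curtis dissimilarity matrix
#'
#' `d(i,j) = sum|x_i - x_j| / sum(x_i + x_j)` between sample abundance
#' profiles; 0 for identical rows, 1 for disjoint supports. All-zero rows are
#' rejected (the dissimilarity is undefined for them).
#'
#' @param matrix Nonnegative samples x taxa matrix.
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (any(matrix < 0)) stop("negative entries are not allowed")
  zero <- rowSums(matrix) == 0
  if (any(zero)) {
    stop("all-zero abundance rows: ",
         paste(rownames(matrix)[zero], collapse = ", "))
  }
  vegan::vegdist(matrix, method = "bray")
}

#' Iterative variance inflation factor filter
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing numeric variable j on all the
#' others; the variable with the largest VIF is dropped repeatedly until all
#' VIFs are at or below the threshold. A perfectly collinear pair loses
#' exactly one member.
#'
#' @param env Data.frame of environmental variables (numeric columns used).
#' @param threshold VIF cutoff (default 5).
#' @return Character vector of retained variable names.
#' @export
vif_filter <- function(env, threshold = 5) {
  num <- names(env)[vapply(env, is.numeric, logical(1))]
  if (length(num) < 2) stop("need at least 2 numeric variables")
  X <- as.data.frame(env[num])
  if (nrow(X) <= length(num)) stop("need more samples than variables")
  vif_of <- function(v, vars) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                            data = X))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  vars <- num
  repeat {
    if (length(vars) < 2) break
    vifs <- vapply(vars, vif_of, numeric(1), vars = vars)
    if (max(vifs) <= threshold) break
    vars <- setdiff(vars, names(which.max(vifs)))
  }
  vars
}

# dbRDA of d on the given variables; formula built in a local environment
fit_dbrda <- function(d, env, vars, condition = NULL, add = FALSE) {
  rhs <- paste(vars, collapse = " + ")
  if (length(condition)) {
    rhs <- paste(rhs, "+ Condition(", paste(condition, collapse = " + "), ")")
  }
  fml <- stats::as.formula(paste(".d ~", rhs))
  .d <- d
  environment(fml) <- environment()
  vegan::dbrda(fml, data = env, add = add)
}

adj_r2 <- function(mod) {
  r <- vegan::RsquareAdj(mod)
  if (!is.null(r$adj.r.squared) && is.finite(r$adj.r.squared)) r$adj.r.squared
  else r$r.squared
}

#' Forward selection of environmental drivers for dbRDA
#'
#' Greedy stepwise addition: at each step candidate variables are ordered by
#' the gain in adjusted constrained variance of the dbRDA, and the best-gain
#' candidate whose partial permutation test (given the already selected
#' variables) has p < alpha is admitted. Selection stops when no candidate is
#' admissible. `alpha >= 1` disables the test so all variables are eventually
#' admitted in decreasing order of marginal gain.
#'
#' @param dist A `dist` of community dissimilarities.
#' @param env Data.frame of imputed (no missing) environmental variables.
#' @param alpha Admission significance level (default 0.05).
#' @param n_perm Number of permutations (>= 19; p uses the (b+1)/(m+1)
#'   estimator).
#' @param seed Integer seed for the permutation tests.
#' @return Data.frame of selected variables in order, with the adjusted-R2
#'   gain and permutation p-value at admission.
#' @export
forward_select <- function(dist, env, alpha = 0.05, n_perm = 999, seed = 1) {
  if (n_perm < 19) stop("n_perm must be at least 19 (p-value resolution)")
  num <- names(env)[vapply(env, is.numeric, logical(1))]
  if (anyNA(env[num])) stop("env contains missing values; impute first")
  env <- as.data.frame(env[num])
  selected <- character(0)
  steps <- list()
  current <- 0
  set.seed(as.integer(seed))
  repeat {
    remaining <- setdiff(num, selected)
    if (!length(remaining)) break
    gains <- vapply(remaining, function(v) {
      adj_r2(fit_dbrda(dist, env, c(selected, v))) - current
    }, numeric(1))
    admitted <- FALSE
    for (v in remaining[order(-gains)]) {
      if (alpha >= 1) {
        p <- NA_real_
      } else {
        part <- fit_dbrda(dist, env, v, condition = selected)
        p <- stats::anova(part, permutations = n_perm)$`Pr(>F)`[1]
      }
      if (alpha >= 1 || (is.finite(p) && p < alpha)) {
        selected <- c(selected, v)
        steps[[length(steps) + 1]] <- data.frame(variable = v, gain = gains[[v]],
                                                 p_value = p)
        current <- current + gains[[v]]
        admitted <- TRUE
        break
      }
    }
    if (!admitted) break
  }
  if (!length(steps)) {
    return(data.frame(variable = character(0), gain = numeric(0),
                      p_value = numeric(0)))
  }
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  out
}

#' Distance-based redundancy analysis
#'
#' Principal coordinates of the dissimilarity matrix followed by redundancy
#' analysis of the retained coordinates on the environmental variables, with
#' a global permutation test of the constrained fraction. Negative
#' eigenvalues of the PCoA are discarded by default, or absorbed with the
#' Lingoes or Cailliez additive correction.
#'
#' @param dist A `dist` of dissimilarities.
#' @param env Data.frame of (VIF-filtered) numeric variables; needs
#'   n > p + 1 and full column rank.
#' @param correction "none", "lingoes", or "cailliez".
#' @param n_perm Permutations for the global test.
#' @param seed Integer seed.
#' @return List of class `dbrda_result`: constrained and unconstrained
#'   eigenvalues, site scores, biplot scores, proportion of variance
#'   constrained, permutation p-value, and the underlying vegan model.
#' @export
dbrda_fit <- function(dist, env, correction = c("none", "lingoes", "cailliez"),
                      n_perm = 999, seed = 1) {
  correction <- match.arg(correction)
  num <- names(env)[vapply(env, is.numeric, logical(1))]
  env <- as.data.frame(env[num])
  n <- attr(dist, "Size")
  if (n <= ncol(env) + 1) stop("need n > p + 1 samples")
  if (qr(scale(as.matrix(env), scale = FALSE))$rank < ncol(env)) {
    stop("environmental variables are rank deficient; filter collinear variables first")
  }
  add <- switch(correction, none = FALSE, lingoes = "lingoes", cailliez = "cailliez")
  mod <- fit_dbrda(dist, env, num, add = add)
  set.seed(as.integer(seed))
  pval <- stats::anova(mod, permutations = n_perm)$`Pr(>F)`[1]
  structure(
    list(
      eig_constrained = mod$CCA$eig,
      eig_unconstrained = mod$CA$eig,
      site_scores = vegan::scores(mod, display = "sites",
                                  choices = seq_len(max(1, mod$CCA$rank))),
      biplot_scores = mod$CCA$biplot,
      proportion_constrained = sum(mod$CCA$eig) / mod$tot.chi,
      p_value = pval,
      n_perm = n_perm,
      correction = correction,
      model = mod
    ),
    class = "dbrda_result"
  )
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat("dbRDA:", length(x$eig_constrained), "constrained axes,",
      sprintf("%.1f%%", 100 * x$proportion_constrained),
      "of variance constrained; permutation p =", format.pval(x$p_value), "\n")
  invisible(x)
}
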