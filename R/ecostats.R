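#' Shannon diversity and equitability of a cover vector
#'
#' `H = -sum p_i log p_i` (natural log, `0 log 0 = 0`) on covers
#' normalized to proportions, and equitability `E = H / log(S)`.  The
#' denominator uses `S = length(cover)` by default — all categories of
#' the scheme, including zero-cover ones — which is the convention that
#' reproduces the published evenness values for these surveys.
#'
#' @param cover nonnegative cover vector (percent or proportions), not
#'   all zero.
#' @param S category count for the `log(S)` denominator (default
#'   `length(cover)`).
#' @return list of class `diversity_result` with `H` (nats), `E`, `S`.
#' @examples
#' shannon(lafac_cover_means()[, "2015"])  # H = 1.14, E = 0.50
#' @export
shannon <- function(cover, S = length(cover)) {
  if (any(cover < 0)) stop("covers must be nonnegative", call. = FALSE)
  if (sum(cover) == 0) stop("all-zero cover vector", call. = FALSE)
  p <- cover / sum(cover)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  structure(list(H = H, E = H / log(S), S = S),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Shannon diversity H = %.2f, equitability E = %.2f (S = %d)\n",
              x$H, x$E, x$S))
  invisible(x)
}

#' Square-root transform a community matrix
#'
#' Element-wise square root, the variance-stabilizing transform applied
#' to percent covers before ANOVA and nMDS.  The transform is recorded
#' in an attribute and applying it twice is an error, guarding against
#' accidental double transformation.
#'
#' @param x nonnegative numeric matrix (or vector).
#' @return transformed matrix with attribute `sqrt_transformed = TRUE`.
#' @export
sqrt_transform <- function(x) {
  if (isTRUE(attr(x, "sqrt_transformed")))
    stop("matrix is already square-root transformed", call. = FALSE)
  if (any(x < 0)) stop("negative covers", call. = FALSE)
  out <- sqrt(x)
  attr(out, "sqrt_transformed") <- TRUE
  out
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant input: normality test undefined", call. = FALSE)
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' One-way ANOVA with Tukey HSD letters for one benthic group
#'
#' Classical one-way ANOVA on (optionally square-root transformed)
#' percent covers across surveys, followed by Tukey's Honest Significant
#' Difference post hoc test.  Survey levels sharing a letter do not
#' differ significantly at `alpha` (the coloring semantics of the
#' box-plot figures).
#'
#' @param values numeric cover values.
#' @param groups factor of survey membership (>= 2 levels with >= 2
#'   replicates each).
#' @param transform `"sqrt"` (default) or `"none"`; vectors already
#'   carrying the `sqrt_transformed` attribute are not re-transformed.
#' @param alpha significance level for the letter grouping.
#' @return list of class `anova_tukey`: `F`, `p`, `tukey` (data frame of
#'   pairwise differences and adjusted p), `letters`.
#' @export
anova_tukey <- function(values, groups, transform = c("sqrt", "none"),
                        alpha = 0.05) {
  transform <- match.arg(transform)
  groups <- factor(groups)
  cnt <- table(groups)
  if (nlevels(groups) < 2L || any(cnt < 2L))
    stop("need >= 2 surveys with >= 2 replicates each", call. = FALSE)
  y <- if (transform == "sqrt" &&
           !isTRUE(attr(values, "sqrt_transformed")))
    sqrt_transform(values) else values
  fit <- stats::aov(as.numeric(y) ~ groups)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$groups
  tkdf <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     lwr = tk[, "lwr"], upr = tk[, "upr"],
                     p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                 df = c(an[1, "Df"], an[2, "Df"]), tukey = tkdf,
                 letters = tukey_letters(levels(groups), tkdf, alpha),
                 transform = transform),
            class = "anova_tukey")
}

## Compact letter display by insert-and-absorb over the non-significant
## pairs.  Comparison labels are matched against explicit level pairs
## because level names may themselves contain the "-" separator.
tukey_letters <- function(levels, tukey, alpha) {
  k <- length(levels)
  ns <- matrix(TRUE, k, k, dimnames = list(levels, levels))
  pairs <- utils::combn(levels, 2)
  for (i in seq_len(nrow(tukey))) {
    hit <- which(paste(pairs[1, ], pairs[2, ], sep = "-") ==
                   tukey$comparison[i] |
                 paste(pairs[2, ], pairs[1, ], sep = "-") ==
                   tukey$comparison[i])
    if (!length(hit))
      stop("cannot resolve Tukey comparison ", tukey$comparison[i],
           call. = FALSE)
    pr <- pairs[, hit[1]]
    if (tukey$p_adj[i] < alpha) ns[pr[1], pr[2]] <- ns[pr[2], pr[1]] <- FALSE
  }
  groups <- list()
  for (l in levels) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(ns[l, groups[[gi]]])) {
        groups[[gi]] <- c(groups[[gi]], l)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- l
  }
  ## absorb: drop any group strictly contained in another
  if (length(groups) > 1L) {
    keep <- rep(TRUE, length(groups))
    for (i in seq_along(groups)) for (j in seq_along(groups))
      if (i != j && keep[j] &&
          all(groups[[i]] %in% groups[[j]]) &&
          length(groups[[i]]) < length(groups[[j]]))
        keep[i] <- FALSE
    groups <- groups[keep]
  }
  out <- stats::setNames(rep("", length(levels)), levels)
  for (gi in seq_along(groups))
    for (l in groups[[gi]]) out[l] <- paste0(out[l], letters[gi])
  out
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s cover): F(%d, %d) = %.3f, p = %.4g\n",
              if (x$transform == "sqrt") "sqrt-transformed" else "raw",
              x$df[1], x$df[2], x$F, x$p))
  cat("Tukey HSD letters:",
      paste(sprintf("%s=%s", names(x$letters), x$letters),
            collapse = ", "), "\n")
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, in \[0, 1\] for
#' nonnegative rows, computed with `vegan::vegdist`.
#'
#' @param x community matrix (samples x categories, nonnegative).
#' @return a `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("community matrix must be nonnegative",
                       call. = FALSE)
  vegan::vegdist(x, method = "bray")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of community differences between groups:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' on the ranked dissimilarities (average ranks for ties), with
#' significance from random relabelings,
#' `p = (1 + #[permuted R >= observed]) / (1 + n_perm)`.  Being
#' rank-based, R is invariant to monotone transforms of the
#' dissimilarities, and untransformed covers are the conventional input.
#' Computed with `vegan::anosim` under a locally seeded RNG, so p is
#' reproducible bit-exactly per seed.
#'
#' @param d `dist` object or community matrix (then Bray-Curtis is
#'   applied).
#' @param grouping factor with >= 2 groups of >= 2 samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list of class `anosim_result`: `R`, `p`, `n_permutations`,
#'   `seed`.
#' @export
anosim <- function(d, grouping, n_perm = 9999L, seed = 1L) {
  if (!inherits(d, "dist")) d <- bray_curtis(d)
  grouping <- factor(grouping)
  cnt <- table(grouping)
  if (nlevels(grouping) < 2L || any(cnt < 2L))
    stop("ANOSIM needs >= 2 groups with >= 2 samples each", call. = FALSE)
  fit <- with_seed(seed, vegan::anosim(d, grouping,
                                       permutations = n_perm))
  structure(list(R = unname(fit$statistic), p = fit$signif,
                 n_permutations = n_perm, seed = as.integer(seed)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, significance = %.4g (%d permutations)\n",
              x$R, x$p, x$n_permutations))
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 nMDS with random restarts plus a metric-scaling
#' start (via `vegan::metaMDS` with `autotransform = FALSE`); the best
#' restart is returned.
#'
#' @param d `dist` object or community matrix (then Bray-Curtis is
#'   applied; transform covers first if desired).
#' @param k ordination dimension (default 2); needs `n >= k + 2`.
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed.
#' @return list of class `nmds_result`: `coordinates` (samples x k),
#'   `stress` (Kruskal stress-1, fraction), `converged`, `n_restarts`.
#' @export
nmds <- function(d, k = 2L, n_restarts = 20L, seed = 1L) {
  if (!inherits(d, "dist")) d <- bray_curtis(d)
  n <- attr(d, "Size")
  if (n < k + 2L) stop("need at least k + 2 samples", call. = FALSE)
  fit <- with_seed(seed, vegan::metaMDS(d, k = k, trymax = n_restarts,
                                        trace = 0, autotransform = FALSE,
                                        wascores = FALSE))
  structure(list(coordinates = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0) ||
                   isTRUE(fit$converged), n_restarts = n_restarts,
                 seed = as.integer(seed)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("nMDS: %d samples in %d dimensions, stress = %.4f%s\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Community matrix from a cover table
#'
#' Reshapes long cover records into the samples x groups percent-cover
#' matrix used by the multivariate analyses; row names are
#' `survey-method.transect`.
#'
#' @param tab a [cover_table()].
#' @param methods methods to keep (default all present).
#' @return numeric matrix with attributes `survey`, `method`,
#'   `transect` (per-row metadata).
#' @export
community_matrix <- function(tab, methods = unique(tab$method)) {
  stopifnot(inherits(tab, "cover_table"))
  tab <- tab[tab$method %in% methods, ]
  if (!nrow(tab)) stop("no rows for the requested methods", call. = FALSE)
  cats <- unique(tab$category)
  key <- interaction(tab$survey, tab$method, tab$transect, drop = TRUE)
  rows <- levels(key)
  m <- matrix(0, length(rows), length(cats),
              dimnames = list(rows, cats))
  m[cbind(match(key, rows), match(tab$category, cats))] <- tab$cover_pct
  meta <- tab[!duplicated(key), c("survey", "method", "transect")]
  meta <- meta[match(rows, unique(key)), ]
  attr(m, "survey") <- meta$survey
  attr(m, "method") <- meta$method
  attr(m, "transect") <- meta$transect
  m
}

#' Community summary report of a survey set
#'
#' Computes the headline community statistics of a monitoring
#' comparison from a cover table: Shannon H and E per survey (from
#' survey mean covers), pairwise ANOSIM between surveys on untransformed
#' covers, and per-group ANOVA + Tukey letters on sqrt-transformed
#' covers.
#'
#' @param tab a [cover_table()]; survey labels should already carry the
#'   method suffix where relevant (e.g. `2019-PQ` vs `2019-DR`).
#' @param n_perm,seed passed to [anosim()].
#' @return list of class `survey_report` with `diversity` (data frame),
#'   `anosim` (data frame of pairwise R and p), `anova` (named list per
#'   group).
#' @export
survey_report <- function(tab, n_perm = 9999L, seed = 1L) {
  stopifnot(inherits(tab, "cover_table"))
  suffixed <- mapply(endsWith, tab$survey, paste0("-", tab$method))
  key <- paste0(tab$survey,
                ifelse(tab$method %in% c("PQ", "DR") & !suffixed,
                       paste0("-", tab$method), ""))
  tab2 <- tab
  tab2$survey <- key
  tab2$method <- "all"
  m <- community_matrix(tab2)
  surveys <- attr(m, "survey")
  ## diversity from survey mean covers
  div <- do.call(rbind, lapply(unique(surveys), function(s) {
    mu <- colMeans(m[surveys == s, , drop = FALSE])
    dv <- shannon(mu)
    data.frame(survey = s, H = round(dv$H, 2), E = round(dv$E, 2))
  }))
  ## pairwise ANOSIM on untransformed covers
  us <- unique(surveys)
  an <- NULL
  if (length(us) >= 2L && all(table(surveys) >= 2L)) {
    for (i in seq_len(length(us) - 1L)) for (j in (i + 1L):length(us)) {
      sel <- surveys %in% us[c(i, j)]
      a <- anosim(m[sel, , drop = FALSE], surveys[sel], n_perm = n_perm,
                  seed = derive_seed(seed, i * 100L + j))
      an <- rbind(an, data.frame(survey_a = us[i], survey_b = us[j],
                                 R = a$R, p = a$p))
    }
  }
  ## per-group ANOVA + letters on sqrt covers
  anova_list <- list()
  if (length(us) >= 2L && all(table(surveys) >= 2L)) {
    for (g in colnames(m))
      anova_list[[g]] <- tryCatch(
        anova_tukey(m[, g], surveys, transform = "sqrt"),
        error = function(e) NULL)
  }
  structure(list(diversity = div, anosim = an, anova = anova_list),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("Diversity by survey:\n")
  print(x$diversity, row.names = FALSE)
  if (!is.null(x$anosim)) {
    cat("\nPairwise ANOSIM (untransformed covers):\n")
    print(transform(x$anosim, R = round(R, 3)), row.names = FALSE)
  }
  if (length(x$anova)) {
    cat("\nTukey letter groups (sqrt covers):\n")
    for (g in names(x$anova))
      if (!is.null(x$anova[[g]]))
        cat(sprintf("  %-42s %s\n", g,
                    paste(sprintf("%s:%s", names(x$anova[[g]]$letters),
                                  x$anova[[g]]$letters), collapse = " ")))
  }
  invisible(x)
}
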