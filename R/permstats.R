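#' Pairwise distance matrix over individuals
#'
#' Builds the symmetric dissimilarity matrix feeding the permutation
#' tests. Rows containing missing feature values are dropped with a
#' warning (e.g. fish whose SDD is undefined).
#'
#' @param X numeric `n x k` feature table (matrix or data.frame); row
#'   names are used as labels when present.
#' @param metric `"manhattan"` (sum of absolute coordinate differences)
#'   or `"euclidean"`.
#' @param labels optional character vector of row labels.
#' @return object of class `distance_matrix`: list with `labels` and the
#'   full symmetric matrix `d` (zero diagonal).
#' @export
distance_matrix <- function(X, metric = c("manhattan", "euclidean"),
                            labels = NULL) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (is.null(labels)) labels <- rownames(X)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(X)))
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with missing features dropped: ",
            paste(labels[!keep], collapse = ", "))
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (nrow(X) < 2L) stop("at least 2 complete rows required")
  d <- as.matrix(dist(X, method = metric))
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d), class = "distance_matrix")
}

# accept distance_matrix / dist / symmetric matrix, return full matrix
as_dist_matrix <- function(x) {
  if (inherits(x, "distance_matrix")) return(x$d)
  if (inherits(x, "dist")) return(as.matrix(x))
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || any(abs(x - t(x)) > 1e-8) ||
      any(diag(x) != 0) || any(x < 0))
    stop("not a valid dissimilarity matrix")
  x
}

# pair index bookkeeping for the upper triangle of an n x n matrix
pair_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)))
  list(idx = ut, i = ((ut - 1L) %% n) + 1L, j = ((ut - 1L) %/% n) + 1L)
}

#' One-way analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test comparing between-group versus
#' within-group dissimilarities. With ranks taken over all
#' `M = n(n-1)/2` dissimilarities (average ranks on ties),
#' `R = (mean rank between - mean rank within) / (M/2)`, bounded in
#' `[-1, 1]`; `R = 1` means complete separation. The p-value uses the
#' `+1` convention: `p = (1 + #permuted R >= observed R) / (1 + n_perm)`,
#' so the smallest attainable p is `1/(n_perm + 1)`.
#'
#' @param d a [distance_matrix()], `dist` object or symmetric matrix.
#' @param grouping group labels, one per row of `d`; every group must
#'   have at least 2 members and there must be at least 2 groups.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `anosim_result`: list with `R`, `p`,
#'   `n_perm`, and the group sizes.
#' @export
anosim <- function(d, grouping, n_perm = 999, seed = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  g <- as.character(grouping)
  if (length(g) != n) stop("grouping length must match matrix size")
  sizes <- table(g)
  if (length(sizes) < 2L) stop("at least 2 groups required")
  if (any(sizes < 2L)) stop("every group must have >= 2 members")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pr <- pair_index(n)
  r <- rank(m[pr$idx])
  M <- length(r)
  stat <- function(gg) {
    w <- gg[pr$i] == gg[pr$j]
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  }
  R_obs <- stat(g)
  R_perm <- vapply(seq_len(n_perm), function(k) stat(g[sample.int(n)]), 0)
  p <- (1 + sum(R_perm >= R_obs)) / (1 + n_perm)
  structure(list(R = R_obs, p = p, n_perm = n_perm,
                 group_sizes = as.integer(sizes),
                 groups = names(sizes)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations, %d groups)\n",
              x$R, x$p, x$n_perm, length(x$groups)))
  invisible(x)
}

# per-stratum pair structures for the crossed two-way scheme
twoway_strata <- function(m, test, strata) {
  lapply(split(seq_len(nrow(m)), strata), function(rows) {
    sub <- m[rows, rows, drop = FALSE]
    pr <- pair_index(length(rows))
    list(g = test[rows], r = rank(sub[pr$idx]),
         i = pr$i, j = pr$j, M = length(pr$idx))
  })
}

twoway_R <- function(st, glist) {
  Rs <- mapply(function(s, gg) {
    w <- gg[s$i] == gg[s$j]
    (mean(s$r[!w]) - mean(s$r[w])) / (s$M / 2)
  }, st, glist)
  mean(Rs)
}

#' Two-way crossed ANOSIM
#'
#' Tests each factor of a crossed two-factor design while controlling for
#' the other: the one-way ANOSIM statistic for factor A is computed
#' separately within every level (stratum) of factor B — ranks taken
#' within the stratum — and averaged across strata; significance comes
#' from permutations of the A labels restricted to within each stratum
#' (and symmetrically for factor B). This is the standard crossed
#' extension of the one-way rank statistic.
#'
#' @inheritParams anosim
#' @param factor_a,factor_b label vectors for the two crossed factors
#'   (e.g. dietary treatment and replicate tank); every combination cell
#'   must be nonempty.
#' @return list of class `anosim_twoway_result` with elements `a` and `b`,
#'   each an `anosim_result` (stratum-averaged `R`, permutation `p`).
#' @export
anosim_twoway <- function(d, factor_a, factor_b, n_perm = 999, seed = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  a <- as.character(factor_a); b <- as.character(factor_b)
  if (length(a) != n || length(b) != n)
    stop("factor lengths must match matrix size")
  if (any(table(a, b) == 0L)) stop("crossed design: every cell must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  one <- function(test, strata) {
    per <- split(seq_len(n), strata)
    for (rows in per)
      if (length(unique(test[rows])) < 2L)
        stop("a stratum with < 2 levels of the tested factor")
    st <- twoway_strata(m, test, strata)
    glist <- lapply(st, `[[`, "g")
    R_obs <- twoway_R(st, glist)
    R_perm <- vapply(seq_len(n_perm), function(k) {
      twoway_R(st, lapply(glist, function(gg) gg[sample.int(length(gg))]))
    }, 0)
    p <- (1 + sum(R_perm >= R_obs)) / (1 + n_perm)
    structure(list(R = R_obs, p = p, n_perm = n_perm,
                   groups = sort(unique(test)),
                   group_sizes = as.integer(table(test))),
              class = "anosim_result")
  }
  structure(list(a = one(a, b), b = one(b, a)),
            class = "anosim_twoway_result")
}

#' @export
print.anosim_twoway_result <- function(x, ...) {
  cat("Two-way crossed ANOSIM\n  factor A: ")
  print(x$a)
  cat("  factor B: ")
  print(x$b)
  invisible(x)
}

#' Pairwise ANOSIM post-hoc comparisons with Bonferroni correction
#'
#' One one-way ANOSIM per unordered pair of groups, restricted to the
#' rows of that pair; adjusted p-values are
#' `min(1, raw p * number of pairs)`.
#'
#' @inheritParams anosim
#' @return data.frame with columns `group1`, `group2`, `R`, `p`, `p_adj`.
#' @export
anosim_pairwise <- function(d, grouping, n_perm = 999, seed = NULL) {
  m <- as_dist_matrix(d)
  g <- as.character(grouping)
  lev <- sort(unique(g))
  if (length(lev) < 3L) stop("pairwise post-hocs need >= 3 groups")
  if (!is.null(seed)) set.seed(seed)
  pairs <- utils::combn(lev, 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(k) {
    sel <- g %in% pairs[, k]
    res <- anosim(m[sel, sel, drop = FALSE], g[sel], n_perm = n_perm)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               R = res$R, p = res$p, p_adj = min(1, res$p * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mantel test of correlation between two distance matrices
#'
#' Permutation test of the association between two dissimilarity matrices
#' over the same individuals. The statistic is the correlation between
#' the two upper triangles — Spearman by default (average ranks on ties).
#' Significance comes from jointly permuting the rows and columns of the
#' second matrix; `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param d_a,d_b distance matrices over the same labels, in the same
#'   order ([distance_matrix()], `dist` or symmetric matrix).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed.
#' @return object of class `mantel_result`: list with `r`, `p`,
#'   `n_perm`, `method`.
#' @export
mantel_test <- function(d_a, d_b, method = c("spearman", "pearson"),
                        n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  ma <- as_dist_matrix(d_a)
  mb <- as_dist_matrix(d_b)
  n <- nrow(ma)
  if (!identical(dim(ma), dim(mb))) stop("matrices must have the same size")
  if (inherits(d_a, "distance_matrix") && inherits(d_b, "distance_matrix") &&
      !identical(d_a$labels, d_b$labels))
    stop("distance matrices are over different labels")
  if (n < 3L) stop("at least 3 individuals required")
  if (!is.null(seed)) set.seed(seed)
  pr <- pair_index(n)
  va <- ma[pr$idx]; vb <- mb[pr$idx]
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stop("constant upper triangle: correlation undefined")
  if (method == "spearman") {
    xa <- rank(va)
    # rank each entry of B once; a joint row/column permutation only
    # re-indexes the multiset of pairs, so ranks are permutation-invariant
    VB <- matrix(0, n, n)
    VB[pr$idx] <- rank(vb)
    VB <- VB + t(VB)
  } else {
    xa <- va
    VB <- mb
  }
  r_obs <- cor(xa, VB[pr$idx])
  r_perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    cor(xa, VB[p, p][pr$idx])
  }, 0)
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, p = p, n_perm = n_perm, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$r, x$p, x$n_perm))
  invisible(x)
}

# compact letter display by insert-and-absorb over significant pairs
cld_insert_absorb <- function(levels_ordered, sig_pairs) {
  cols <- list(levels_ordered)
  if (nrow(sig_pairs) > 0) for (k in seq_len(nrow(sig_pairs))) {
    gi <- sig_pairs[k, 1]; gj <- sig_pairs[k, 2]
    newcols <- list()
    for (cc in cols) {
      if (gi %in% cc && gj %in% cc) {
        newcols <- c(newcols, list(setdiff(cc, gi)), list(setdiff(cc, gj)))
      } else newcols <- c(newcols, list(cc))
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(newcols))
    for (u in seq_along(newcols)) for (v in seq_along(newcols)) {
      if (u != v && keep[u] && keep[v] &&
          all(newcols[[u]] %in% newcols[[v]]) &&
          !(all(newcols[[v]] %in% newcols[[u]]) && u < v))
        keep[u] <- FALSE
    }
    cols <- newcols[keep]
  }
  # order columns by the best-ranked group they contain, then letter them
  first <- vapply(cols, function(cc) min(match(cc, levels_ordered)), 0)
  cols <- cols[order(first)]
  lt <- vapply(levels_ordered, function(g) {
    paste0(letters[which(vapply(cols, function(cc) g %in% cc, TRUE))],
           collapse = "")
  }, "")
  lt
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical one-way ANOVA on a growth trait (total length or weight)
#' followed by Tukey honest significant difference post-hocs; groups are
#' lettered with the insert-and-absorb algorithm so that groups sharing a
#' letter do not differ significantly at `alpha`.
#'
#' @param values numeric per-fish trait values.
#' @param groups treatment labels (one per value); at least 2 groups with
#'   at least 2 observations each.
#' @param alpha significance level for the letter display (default 0.05).
#' @return object of class `anova_cld`: list with `F`, `p`, `df`
#'   (numerator, denominator), a `table` data.frame (`group`, `n`,
#'   `mean`, `sd`, `letters`, ordered by decreasing mean) and the full
#'   Tukey pair table.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups required")
  if (any(table(g) < 2L)) stop("every group needs >= 2 observations")
  if (all(tapply(values, g, function(v) stats::var(v) == 0)))
    stop("zero within-group variance everywhere: F undefined")
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  Fstat <- tab[["F value"]][1]
  pval <- tab[["Pr(>F)"]][1]
  tuk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  means <- tapply(values, g, mean)
  ord <- names(sort(means, decreasing = TRUE))
  sig <- pairs[tuk[, "p adj"] < alpha, , drop = FALSE]
  lt <- cld_insert_absorb(ord, sig)
  table <- data.frame(group = ord, n = as.integer(table(g)[ord]),
                      mean = as.numeric(means[ord]),
                      sd = as.numeric(tapply(values, g, sd)[ord]),
                      letters = lt, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(F = Fstat, p = pval,
                 df = c(tab$Df[1], tab$Df[2]),
                 table = table,
                 tukey = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                                    diff = tuk[, "diff"],
                                    p_adj = tuk[, "p adj"],
                                    row.names = NULL)),
            class = "anova_cld")
}

#' @export
print.anova_cld <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$table, digits = 4)
  invisible(x)
}
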