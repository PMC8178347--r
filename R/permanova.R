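#' Bray-Curtis distance matrix between sample profiles
#'
#' @param composition Long tibble with one row per (sample, taxon):
#'   columns `sample`, `taxon`, `abundance`. If a `rank` column is
#'   present it must contain a single rank (filter first, or pass
#'   `rank`).
#' @param rank Optional rank to filter on when `composition` has a `rank`
#'   column.
#' @return A `stats::dist` object over the samples, Bray-Curtis over the
#'   taxon union (absent taxa count as zero).
#' @export
bray_curtis_matrix <- function(composition, rank = NULL) {
  composition <- as_tibble(composition)
  if ("rank" %in% names(composition)) {
    if (!is.null(rank)) {
      composition <- dplyr::filter(composition, .data$rank == !!rank)
    }
    if (length(unique(composition$rank)) > 1) {
      abort("composition mixes ranks; pass rank= to select one")
    }
  }
  wide <- tidyr::pivot_wider(
    composition[, c("sample", "taxon", "abundance")],
    names_from = "taxon", values_from = "abundance", values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  if (nrow(m) < 2) abort("need at least two samples")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(wide$sample, wide$sample))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  stats::as.dist(d)
}

# all permutations of 1..n as an (n! x n) matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, ifelse(sub[i, ] >= k, sub[i, ] + 1L, sub[i, ]))
      row <- row + 1L
    }
  }
  out
}

#' Multi-factor PERMANOVA with sequential sums of squares
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the distance matrix is Gower-centred (`G = C (-D^2/2) C` with `C` the
#' centring matrix), total sum of squares is `tr(G)`, and each factor's
#' sum of squares is the increase in `tr(H G)` as its dummy columns enter
#' the model in the declared order (sequential, Type-I decomposition).
#' Pseudo-F tests each term against the residual mean square. The p-value
#' comes from free permutation of the samples: with sampled permutations
#' `p = (1 + #\{F* >= F\}) / (1 + n_perm)`; in exact mode all `n!`
#' permutations are enumerated (identity included) and `p` is the exact
#' tail fraction.
#'
#' @param d A `dist` or symmetric distance matrix with sample labels.
#' @param design Data frame with a `sample` column matching the labels of
#'   `d` plus one column per factor.
#' @param factors Factor columns in entry order; defaults to every
#'   non-`sample` column of `design`.
#' @param n_perm Number of random permutations (sampled mode).
#' @param seed Integer seed (sampled mode).
#' @param method `"sampled"` or `"exact"` (exact requires <= 8 samples).
#' @return A `permanova` object; its `table` is a tibble with rows for
#'   each term plus Residuals and Total, columns `term`, `df`, `ss`, `ms`,
#'   `f`, `r2`, `p`.
#' @export
permanova <- function(d, design, factors = NULL, n_perm = 10000, seed = 1,
                      method = c("sampled", "exact")) {
  method <- match.arg(method)
  D <- as.matrix(d)
  n <- nrow(D)
  design <- as_tibble(design)
  if (!"sample" %in% names(design)) abort("design needs a sample column")
  if (!setequal(design$sample, rownames(D))) {
    abort("design samples do not match distance matrix labels")
  }
  design <- design[match(rownames(D), design$sample), ]
  factors <- factors %||% setdiff(names(design), "sample")
  for (f in factors) {
    if (length(unique(design[[f]])) < 2) {
      abort(paste0("factor ", f, " has fewer than 2 levels"))
    }
  }
  # Gower-centred inner-product matrix
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))
  # cumulative hat matrices, intercept first
  X <- matrix(1, n, 1)
  hats <- list()
  dfs <- integer(length(factors))
  rank_prev <- 1L
  for (j in seq_along(factors)) {
    X <- cbind(X, stats::model.matrix(~ 0 + factor(design[[factors[j]]])))
    q <- qr(X)
    dfs[j] <- q$rank - rank_prev
    rank_prev <- q$rank
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[j]] <- Q %*% t(Q)
  }
  df_res <- n - rank_prev
  if (any(dfs < 1)) abort("aliased factor: no degrees of freedom left")
  if (df_res < 1) abort("no residual degrees of freedom")
  if (n < sum(dfs) + 2) abort("too few samples for the model")

  # tr(H_j G) for the cumulative hats; the intercept contributes zero on
  # the centred G, so sequential SS are successive differences from zero
  stats_for <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    f <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stats_for(G)
  f_thresh <- obs$f - (abs(obs$f) * 1e-9 + 1e-12)

  if (method == "exact") {
    if (n > 8) abort("exact enumeration supported for <= 8 samples")
    perms <- all_permutations(n)
    fstar <- matrix(0, nrow(perms), length(factors))
    for (i in seq_len(nrow(perms))) {
      fstar[i, ] <- stats_for(G[perms[i, ], perms[i, ]])$f
    }
    pvals <- colMeans(sweep(fstar, 2, f_thresh, ">="))
    n_perm_used <- nrow(perms)
  } else {
    exceed <- numeric(length(factors))
    withr::with_seed(seed, {
      for (i in seq_len(n_perm)) {
        p <- sample(n)
        exceed <- exceed + (stats_for(G[p, p])$f >= f_thresh)
      }
    })
    pvals <- (1 + exceed) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  table <- dplyr::bind_rows(
    tibble(term = factors, df = dfs, ss = obs$ss, ms = obs$ss / dfs,
           f = obs$f, r2 = obs$ss / ss_total, p = pvals),
    tibble(term = "Residuals", df = df_res, ss = obs$ss_res,
           ms = obs$ss_res / df_res, f = NA_real_,
           r2 = obs$ss_res / ss_total, p = NA_real_),
    tibble(term = "Total", df = n - 1L, ss = ss_total, ms = NA_real_,
           f = NA_real_, r2 = 1, p = NA_real_))
  structure(list(table = table, n = n, n_perm = n_perm_used,
                 method = method, seed = seed, factors = factors),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$method, ", ", x$n_perm, " permutations, n = ",
      x$n, ")\n", sep = "")
  tab <- as.data.frame(x$table)
  names(tab) <- c("Term", "Df", "SS", "MS", "F.Model", "R2", "Pr(>F)")
  print(tab, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Tidy a PERMANOVA fit
#' @param x A `permanova` object.
#' @param ... Unused.
#' @return The decomposition table as a tibble.
#' @exportS3Method generics::tidy
tidy.permanova <- function(x, ...) x$table

#' One-row summary of a PERMANOVA fit
#' @param x A `permanova` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_perm`, `method`, `r2_model` (summed term
#'   R-squared) and the smallest term p-value.
#' @exportS3Method generics::glance
glance.permanova <- function(x, ...) {
  terms <- dplyr::filter(x$table, !.data$term %in% c("Residuals", "Total"))
  tibble(n = x$n, n_perm = x$n_perm, method = x$method,
         r2_model = sum(terms$r2), p_min = min(terms$p))
}

#' Recompute the derived columns of a PERMANOVA table
#'
#' Given term rows with degrees of freedom and sums of squares (plus a
#' Residuals row), recomputes mean squares (`ss/df`), pseudo-F (term MS
#' over residual MS) and R-squared (`ss / ss_total`). Used to check the
#' internal consistency of published PERMANOVA tables from their printed
#' SS and Df columns.
#'
#' @param table Data frame with columns `term`, `df`, `ss`; must contain a
#'   `Residuals` row. A `Total` row is used for `ss_total` when present,
#'   otherwise `ss_total = sum(ss)`.
#' @return Tibble with columns `term`, `df`, `ss`, `ms`, `f`, `r2`.
#' @export
permanova_recompute <- function(table) {
  table <- as_tibble(table)
  stopifnot(all(c("term", "df", "ss") %in% names(table)))
  if (!"Residuals" %in% table$term) abort("table needs a Residuals row")
  total <- if ("Total" %in% table$term) {
    table$ss[table$term == "Total"]
  } else sum(table$ss)
  body <- dplyr::filter(table, .data$term != "Total")
  ms_res <- body$ss[body$term == "Residuals"] /
    body$df[body$term == "Residuals"]
  body <- dplyr::mutate(body, ms = .data$ss / .data$df)
  dplyr::transmute(body, term = .data$term, df = .data$df, ss = .data$ss,
    ms = .data$ms,
    f = ifelse(.data$term == "Residuals", NA_real_, .data$ms / ms_res),
    r2 = .data$ss / total)
}
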