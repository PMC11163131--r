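check_xy <- function(x, y) {
  if (length(x) != length(y)) {
    stop(errorCondition("x and y must have equal length",
                        class = c("topoqspr_degenerate_input", "error")))
  }
  if (length(x) < 3L) {
    stop(errorCondition("need at least 3 observations for a meaningful fit",
                        class = c("topoqspr_degenerate_input", "error")))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("zero variance in x or y",
                        class = c("topoqspr_degenerate_input", "error")))
  }
  invisible(TRUE)
}

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper over \code{stats::cor}: symmetric in its
#' arguments and invariant under affine rescaling of either one. Inputs of
#' length < 3 or with zero variance are rejected rather than returning
#' \eqn{\pm 1}.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y)
  stats::cor(x, y)
}

#' Simple linear regression with the QSPR summary statistics
#'
#' Ordinary least squares of \code{y} on \code{x} (property = c + m * index)
#' via \code{stats::lm}, returning the statistics reported in descriptor-
#' property screening tables: sample size N, intercept c, slope m, Pearson
#' r, r-squared, the regression F statistic on (1, N-2) degrees of freedom,
#' its upper-tail p-value, and a significance indicator at the conventional
#' p < 0.05 level.
#'
#' @inheritParams pearson_r
#' @return object of class \code{qspr_fit}: a list with elements \code{n},
#'   \code{c}, \code{m}, \code{r}, \code{r2}, \code{f_stat}, \code{p_value},
#'   \code{indicator}, and the underlying \code{lm} fit as \code{model}.
#' @examples
#' f <- fit_simple_linear(c(0, 1, 2), c(5, 7, 9))
#' f$c; f$m; f$r
#' @export
fit_simple_linear <- function(x, y) {
  check_xy(x, y)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  n <- length(x)
  r2 <- r * r
  f_stat <- r2 * (n - 2) / (1 - r2)
  p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(
    n = n, c = unname(co[1]), m = unname(co[2]),
    r = r, r2 = r2, f_stat = f_stat, p_value = p,
    indicator = if (p < 0.05) "Significant" else "Not significant",
    model = fit
  ), class = "qspr_fit")
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf("y = %.4f + %.4f x   (N=%d, r=%.4f, r2=%.4f, F=%.4f, p=%.3g, %s)\n",
              x$c, x$m, x$n, x$r, x$r2, x$f_stat, x$p_value, x$indicator))
  invisible(x)
}

#' Predict a property from a fitted index regression
#'
#' @param fit a \code{qspr_fit}.
#' @param index_value topological index value(s) of the query structure(s).
#' @return predicted property value(s) c + m * index_value.
#' @export
predict_property <- function(fit, index_value) {
  stopifnot(inherits(fit, "qspr_fit"))
  fit$c + fit$m * index_value
}

#' Fit the full index-by-property regression grid
#'
#' One simple linear regression per (topological index, property) pair.
#' With \code{index_source = "table2"} the predictors are the published
#' reference index values (the reproduction mode: those are the numbers the
#' source screening actually regressed on, some of them rounded); with
#' \code{"computed"} the indices are recomputed from the fixture structures
#' (the scientific mode).
#'
#' @param records an \code{eye_drug_set} (default: the bundled benchmark).
#' @param index_source \code{"table2"} or \code{"computed"}.
#' @inheritParams edge_weight
#' @return object of class \code{qspr_table}: data.frame with one row per
#'   (index, property) cell and columns \code{index}, \code{property},
#'   \code{n}, \code{c}, \code{m}, \code{r}, \code{r2}, \code{f_stat},
#'   \code{p_value}, \code{indicator}. Attributes record the index source
#'   and FRR variant.
#' @export
fit_all <- function(records = load_eye_drugs(),
                    index_source = c("table2", "computed"),
                    frr_variant = c("as_stated", "as_tabulated")) {
  index_source <- match.arg(index_source)
  frr_variant <- match.arg(frr_variant)
  if (length(records) < 3L) {
    stop(errorCondition("need at least 3 records",
                        class = c("topoqspr_degenerate_input", "error")))
  }
  X <- if (index_source == "table2") {
    drug_reference_matrix(records)
  } else {
    graphs <- lapply(records, function(r) mol_graph_from_smiles(r$smiles, r$name))
    compute_index_table(graphs, frr_variant = frr_variant)
  }
  Y <- drug_property_matrix(records)
  props <- colnames(Y)[-1]
  grid <- list()
  for (ix in topo_indices()) {
    for (p in props) {
      f <- fit_simple_linear(X[[ix]], Y[[p]])
      grid[[length(grid) + 1L]] <- data.frame(
        index = ix, property = p, n = f$n, c = f$c, m = f$m, r = f$r,
        r2 = f$r2, f_stat = f$f_stat, p_value = f$p_value,
        indicator = f$indicator, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, grid)
  rownames(out) <- NULL
  attr(out, "index_source") <- index_source
  attr(out, "frr_variant") <- frr_variant
  class(out) <- c("qspr_table", "data.frame")
  out
}

#' Best-correlated index per property
#'
#' @param table a \code{qspr_table} from \code{\link{fit_all}}.
#' @return data.frame with columns \code{property}, \code{index}, \code{r}:
#'   for each property the index with maximal Pearson r, ties broken by the
#'   canonical index order M1..SRR.
#' @export
best_index_report <- function(table) {
  stopifnot(inherits(table, "data.frame"),
            all(c("index", "property", "r") %in% names(table)))
  order_ix <- topo_indices()
  props <- unique(table$property)
  rows <- lapply(props, function(p) {
    sub <- table[table$property == p, ]
    sub <- sub[order(match(sub$index, order_ix)), ]
    best <- sub[which.max(sub$r), ]   # which.max takes the first maximum
    data.frame(property = p, index = best$index, r = best$r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression equations in report form
#'
#' @param table a \code{qspr_table}.
#' @param digits rounding for display (computation is never rounded).
#' @return character vector of lines "PROP = c + m*INDEX".
#' @export
equation_listing <- function(table, digits = 4) {
  stopifnot(inherits(table, "qspr_table"))
  sprintf("%s = %s + %s*%s",
          table$property,
          formatC(round_half_up(table$c, digits), format = "f", digits = digits),
          formatC(round_half_up(table$m, digits), format = "f", digits = digits),
          table$index)
}
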