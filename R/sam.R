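#' Social accounting matrix
#'
#' A SAM records every monetary flow of an economy as a square nonnegative
#' matrix over named accounts: cell `(i, j)` is the payment received by
#' account `i` from account `j`. In a consistent SAM each account's income
#' (row total) equals its expenditure (column total). Flows here are in
#' hundred-million RMB, the unit of the shipped Beijing matrix.
#'
#' @param flows Square numeric matrix with identical row/column names, or a
#'   data frame whose first column holds the account names.
#' @return A `sam` object (a named matrix).
#' @export
sam <- function(flows) {
  if (is.data.frame(flows)) {
    acc <- as.character(flows[[1]])
    flows <- as.matrix(flows[-1])
    rownames(flows) <- acc
  }
  flows <- as.matrix(flows)
  if (nrow(flows) != ncol(flows)) abort("a SAM must be square.")
  if (any(flows < 0)) abort("SAM flows must be nonnegative.")
  if (is.null(rownames(flows))) abort("SAM accounts must be named.")
  colnames(flows) <- colnames(flows) %||% rownames(flows)
  if (!identical(rownames(flows), colnames(flows))) {
    abort("row and column accounts must match.")
  }
  structure(flows, class = c("sam", "matrix", "array"))
}

#' @rdname sam
#' @param path CSV file: header row of account names, first column of account
#'   names, numeric flows.
#' @export
load_sam <- function(path) {
  sam(readr::read_csv(path, show_col_types = FALSE))
}

#' @export
print.sam <- function(x, ...) {
  cat("Social accounting matrix,", nrow(x), "accounts\n")
  print(unclass(round(x, 2)))
  imb <- sam_imbalance(x)
  worst <- max(abs(imb$relative_imbalance), na.rm = TRUE)
  cat(sprintf("max |row - col| / col: %.2e\n", worst))
  invisible(x)
}

#' Account-level imbalance report
#'
#' @param x A [sam()].
#' @return Tibble `account, row_total, col_total, imbalance,
#'   relative_imbalance`.
#' @export
sam_imbalance <- function(x) {
  rt <- rowSums(x)
  ct <- colSums(x)
  tibble(
    account = rownames(x), row_total = rt, col_total = ct,
    imbalance = rt - ct,
    relative_imbalance = ifelse(ct > 0, (rt - ct) / ct, ifelse(rt > 0, Inf, 0))
  )
}

is_balanced <- function(x, tol = 1e-8) {
  imb <- sam_imbalance(x)
  all(abs(imb$relative_imbalance[is.finite(imb$relative_imbalance)]) < tol) &&
    !any(is.infinite(imb$relative_imbalance))
}

#' Rebalance a SAM by biproportional (RAS) scaling
#'
#' Published SAMs are often off by rounding in a few cells. RAS alternately
#' scales rows and columns toward common account totals (the mean of the
#' row and column total per account) until every account balances. Zero cells
#' stay zero, so the flow topology is preserved.
#'
#' @param x A [sam()].
#' @param tol Convergence tolerance on `max |row - col| / col`.
#' @param max_iter Iteration cap.
#' @return The balanced `sam`.
#' @examples
#' rebalance_sam(beijing_sam())
#' @export
rebalance_sam <- function(x, tol = 1e-8, max_iter = 10000L) {
  S <- unclass(x)
  for (i in seq_len(max_iter)) {
    # target totals are refreshed from the current matrix: with sparse SAM
    # topologies (single-cell rows/columns) fixed targets are infeasible, and
    # letting them drift diffuses rounding imbalances around the account cycle
    target <- (rowSums(S) + colSums(S)) / 2
    rs <- rowSums(S)
    S <- S * ifelse(rs > 0, target / rs, 1)
    cs <- colSums(S)
    S <- sweep(S, 2, ifelse(cs > 0, target / cs, 1), `*`)
    rel <- abs(rowSums(S) - colSums(S)) / pmax(colSums(S), .Machine$double.eps)
    if (max(rel) < tol) {
      return(sam(S))
    }
  }
  abort("RAS did not converge; the flow topology may be infeasible.")
}
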