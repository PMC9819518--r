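# Random consistency indices by matrix size, as used by the C.R. test.
# "printed" is the lookup shipped with the framework tables; "saaty_classic"
# differs at n = 12 (1.54 instead of 1.48).
ri_tables <- list(
  printed = c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
              1.51, 1.48, 1.56, 1.57, 1.59),
  saaty_classic = c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
                    1.51, 1.54, 1.56, 1.57, 1.59)
)

#' Validate a Saaty pairwise comparison matrix
#'
#' A pairwise comparison matrix (PCM) records expert judgments on
#' Saaty's nine-point ratio scale: entry \eqn{a_{ij}} says how much more
#' important criterion *i* is than criterion *j*, so the diagonal is 1,
#' \eqn{a_{ji} = 1/a_{ij}}, and every entry lies in \eqn{[1/9, 9]}.
#' Violations are reported by position and label; nothing is silently
#' repaired.
#'
#' @param matrix Square numeric matrix of positive judgments.
#' @param labels Character vector of criterion codes, one per row.
#' @param tol Absolute tolerance for the diagonal and reciprocity checks.
#' @return An object of class `pcm` (fields `labels`, `matrix`).
#' @export
pcm <- function(matrix, labels = rownames(matrix), tol = 1e-9) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    abort("judgment matrix must be square")
  }
  n <- nrow(matrix)
  if (n < 2) abort("judgment matrix needs at least 2 criteria")
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  if (length(labels) != n) abort("labels must match matrix size")
  if (any(!is.finite(matrix)) || any(matrix <= 0)) {
    abort("judgment entries must be positive and finite")
  }
  if (any(abs(diag(matrix) - 1) > tol)) {
    abort(sprintf("non-unit diagonal at: %s",
                  paste(labels[abs(diag(matrix) - 1) > tol], collapse = ", ")))
  }
  scale_tol <- 1e-6  # printed scales carry at most a few decimals
  if (any(matrix > 9 + scale_tol | matrix < 1 / 9 - scale_tol)) {
    idx <- which(matrix > 9 + scale_tol | matrix < 1 / 9 - scale_tol, arr.ind = TRUE)[1, ]
    abort(sprintf("entry (%s, %s) = %g outside Saaty scale [1/9, 9]",
                  labels[idx[1]], labels[idx[2]], matrix[idx[1], idx[2]]))
  }
  recip <- abs(matrix - 1 / t(matrix))
  if (any(recip > tol)) {
    idx <- which(recip > tol, arr.ind = TRUE)[1, ]
    abort(sprintf("reciprocity violated for (%s, %s): %g vs 1/%g",
                  labels[idx[1]], labels[idx[2]],
                  matrix[idx[2], idx[1]], matrix[idx[1], idx[2]]))
  }
  m <- unname(matrix)
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, matrix = m), class = "pcm")
}

#' @rdname pcm
#' @export
validate_pcm <- pcm

#' @export
print.pcm <- function(x, ...) {
  cat(sprintf("<pcm> %d criteria: %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  print(round(x$matrix, 3))
  invisible(x)
}

#' AHP priority vector of a pairwise comparison matrix
#'
#' The default `"npcm"` method is the normalized-PCM construction:
#' divide each column by its sum, then average across each row.  For a
#' perfectly consistent matrix (\eqn{a_{ij} = w_i / w_j}) it recovers
#' the weights exactly.  `"eigen"` returns the principal right
#' eigenvector instead, the classical alternative; the two agree for
#' consistent matrices and differ slightly otherwise.
#'
#' @param x A [pcm].
#' @param method `"npcm"` (column-normalize/row-average, the default) or
#'   `"eigen"` (principal eigenvector).
#' @return Numeric weights named by the criterion labels, summing to 1.
#' @export
priority_vector <- function(x, method = c("npcm", "eigen")) {
  stopifnot(inherits(x, "pcm"))
  method <- rlang::arg_match(method)
  A <- x$matrix
  w <- switch(method,
    npcm = rowMeans(sweep(A, 2, colSums(A), `/`)),
    eigen = {
      ev <- eigen(A)
      v <- Re(ev$vectors[, which.max(Re(ev$values))])
      v <- abs(v)
      v / sum(v)
    }
  )
  setNames(as.numeric(w), x$labels)
}

#' Maximum-eigenvalue estimate from a weight vector
#'
#' Computes \eqn{\lambda_{max}} as the mean over rows of
#' \eqn{(A w)_i / w_i}; for a consistent matrix this equals *n* exactly.
#'
#' @param x A [pcm].
#' @param weights Strictly positive weights summing to 1.
#' @return The \eqn{\lambda_{max}} estimate.
#' @export
ahp_lambda_max <- function(x, weights) {
  stopifnot(inherits(x, "pcm"))
  if (any(weights <= 0)) abort("weights must be strictly positive")
  mean((x$matrix %*% weights) / weights)
}

#' AHP weights with consistency report
#'
#' Derives the priority vector and gates it with the consistency-ratio
#' test: \eqn{C.I. = (\lambda_{max} - n)/(n - 1)},
#' \eqn{C.R. = C.I. / R.I.} with the size-dependent random index
#' \eqn{R.I.}, accepted when \eqn{C.R. < 0.1}.  Matrices of size
#' \eqn{n \le 2} cannot be inconsistent; their C.R. is defined as 0.
#'
#' @inheritParams priority_vector
#' @param ri_table Which random-index lookup to use (see `ri_tables`);
#'   covers \eqn{n \le 15}.
#' @param ri Explicit random index, required for \eqn{n > 15}.
#' @return An object of class `ahp_weights` with fields `labels`,
#'   `weights`, `n`, `lambda_max`, `ci`, `ri`, `cr`, `acceptable`,
#'   `method`.
#' @export
ahp_weights <- function(x, method = c("npcm", "eigen"),
                        ri_table = c("printed", "saaty_classic"), ri = NULL) {
  stopifnot(inherits(x, "pcm"))
  method <- rlang::arg_match(method)
  ri_table <- rlang::arg_match(ri_table)
  n <- length(x$labels)
  w <- priority_vector(x, method)
  lm <- ahp_lambda_max(x, w)
  if (n <= 2) {
    ci <- 0
    ri_val <- ri %||% 0
    cr <- 0
  } else {
    ci <- (lm - n) / (n - 1)
    ri_val <- ri %||% {
      if (n > length(ri_tables[[ri_table]])) {
        abort(sprintf("no tabulated random index for n = %d; supply `ri`", n))
      }
      ri_tables[[ri_table]][n]
    }
    cr <- ci / ri_val
  }
  structure(
    list(labels = x$labels, weights = w, n = n, lambda_max = lm,
         ci = ci, ri = ri_val, cr = cr, acceptable = cr < 0.1,
         method = method),
    class = "ahp_weights"
  )
}

#' @export
print.ahp_weights <- function(x, ...) {
  cat(sprintf("<ahp_weights> n = %d (%s)\n", x$n, x$method))
  print(round(x$weights, 4))
  cat(sprintf("  lambda_max = %.4f, C.I. = %.4f, R.I. = %.2f, C.R. = %.4f (%s)\n",
              x$lambda_max, x$ci, x$ri, x$cr,
              if (x$acceptable) "acceptable" else "NOT acceptable"))
  invisible(x)
}

#' @method tidy ahp_weights
#' @export
tidy.ahp_weights <- function(x, ...) {
  tibble(code = x$labels, weight = unname(x$weights))
}

#' @method glance ahp_weights
#' @export
glance.ahp_weights <- function(x, ...) {
  tibble(n = x$n, lambda_max = x$lambda_max, ci = x$ci, ri = x$ri,
         cr = x$cr, acceptable = x$acceptable, method = x$method)
}

#' Indicator weights for a whole framework
#'
#' Runs [ahp_weights()] on every judgment group and assembles one weight
#' per indicator.  Group labels must exactly partition the framework's
#' indicator codes; any group with \eqn{C.R. \ge 0.1} aborts the run,
#' naming the group.  By default exported weights are rounded to two
#' decimals, the precision at which practitioners publish and reuse AHP
#' weight tables (and the precision at which the bundled worked example
#' is reproduced); pass `digits = NULL` for full precision.
#'
#' @param fw A [framework()].
#' @param pcms Named list of [pcm] objects; defaults to the framework's.
#' @param digits Decimals to round exported weights to (`NULL` = none).
#' @param method Passed to [ahp_weights()].
#' @param ri_table Passed to [ahp_weights()].
#' @return Tibble with one row per indicator: `code`, `group`, `weight`,
#'   and the group's `lambda_max`, `ci`, `ri`, `cr`.
#' @export
weights_for_framework <- function(fw, pcms = NULL, digits = 2,
                                  method = "npcm", ri_table = "printed") {
  stopifnot(inherits(fw, "his_framework"))
  pcms <- pcms %||% fw$pcms
  if (!length(pcms)) abort("no judgment groups supplied")
  codes <- fw$indicators$code
  covered <- unlist(purrr::map(pcms, "labels"))
  if (anyDuplicated(covered)) {
    abort(sprintf("indicator(s) appear in more than one judgment group: %s",
                  paste(unique(covered[duplicated(covered)]), collapse = ", ")))
  }
  missing <- setdiff(codes, covered)
  if (length(missing)) {
    abort(sprintf("no judgment group covers indicator(s): %s",
                  paste(missing, collapse = ", ")))
  }
  stray <- setdiff(covered, codes)
  if (length(stray)) {
    abort(sprintf("judgment group label(s) not in framework: %s",
                  paste(stray, collapse = ", ")))
  }
  rows <- purrr::imap(pcms, \(p, g) {
    fit <- ahp_weights(p, method = method, ri_table = ri_table)
    if (!fit$acceptable) {
      abort(sprintf(
        "judgment group '%s' fails the consistency test: C.R. = %.3f >= 0.1 (lambda_max = %.3f, C.I. = %.3f, R.I. = %.2f)",
        g, fit$cr, fit$lambda_max, fit$ci, fit$ri))
    }
    w <- if (is.null(digits)) fit$weights else round_half_up(fit$weights, digits)
    tibble(code = fit$labels, group = g, weight = unname(w),
           lambda_max = fit$lambda_max, ci = fit$ci, ri = fit$ri, cr = fit$cr)
  })
  out <- dplyr::bind_rows(rows)
  out[match(codes, out$code), ]
}
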