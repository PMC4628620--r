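#' Kinship matrix and inbreeding coefficients from a pedigree
#'
#' Computes the full kinship matrix \eqn{\Phi} and the per-individual
#' inbreeding coefficients \eqn{F} by the standard recursive (Emik--Terrill)
#' tabular method, exact given the pedigree.  Processing individuals in
#' topological order (parents first), with founders taken as non-inbred and
#' mutually unrelated:
#' \deqn{\Phi_{ii} = \tfrac12 (1 + \Phi_{f_i m_i}), \qquad
#'       \Phi_{ij} = \tfrac12 (\Phi_{f_i j} + \Phi_{m_i j})}
#' for any \eqn{j} preceding \eqn{i}, and \eqn{F_i = \Phi_{f_i m_i}}
#' (0 for founders).  The additive genetic covariance between relatives used
#' by [polygenic()] is \eqn{2\Phi\sigma^2_g}; the doubling is applied by the
#' model, never here.
#'
#' @param ped a [pedigree()].
#' @return An object of class `kinship_result`: list with `ids`, `phi`
#'   (symmetric n x n matrix with dimnames), and `F` (named vector).
#' @examples
#' ped <- pedigree(c("F", "M", "C"), c("0", "0", "F"), c("0", "0", "M"),
#'                 c(1, 2, 1))
#' kin <- kinship(ped)
#' kin$phi["F", "C"]   # parent-offspring kinship: 0.25
#' @export
kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fi <- unname(idx[ped$father])
  mi <- unname(idx[ped$mother])
  if (any(stats::na.omit(fi >= idx) | stats::na.omit(mi >= idx)))
    stop("pedigree is not in topological order")  # contract: pedigree() sorts

  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fi[i]; m <- mi[i]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        row <- 0.5 * (phi[f, j] + phi[m, j])
        phi[i, j] <- row
        phi[j, i] <- row
      }
      phi[i, i] <- 0.5 * (1 + phi[f, m])
    }
  }
  Fcoef <- 2 * diag(phi) - 1
  names(Fcoef) <- ped$id
  structure(list(ids = ped$id, phi = phi, F = Fcoef),
            class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  n <- length(x$ids)
  off <- x$phi[upper.tri(x$phi)]
  cat(sprintf("Kinship for %d individuals\n", n))
  cat(sprintf("  median pairwise phi: %.4g  (nonzero pairs: %.1f%%)\n",
              stats::median(off), 100 * mean(off > 0)))
  cat(sprintf("  inbred individuals (F > 0): %d; median F among inbred: %s\n",
              sum(x$F > 0),
              if (any(x$F > 0)) sprintf("%.4g", stats::median(x$F[x$F > 0]))
              else "-"))
  invisible(x)
}

#' Inbreeding quartile classes
#'
#' Individuals with exactly zero inbreeding form class `C0`; the strictly
#' positive coefficients are split at their own 25/50/75th percentiles into
#' `Q1`--`Q4` (the distribution of F is heavily skewed, so quartiles of the
#' nonzero part are used rather than cuts of the full vector).  A value lying
#' exactly on a percentile boundary goes to the lower class.
#'
#' @param F numeric vector of inbreeding coefficients, all `>= 0`.
#' @return factor with levels `C0, Q1, Q2, Q3, Q4`.
#' @export
inbreeding_classes <- function(F) {
  if (any(is.na(F)) || any(F < 0))
    stop("inbreeding coefficients must be non-negative and non-missing")
  out <- rep("C0", length(F))
  pos <- F > 0
  if (any(pos)) {
    qs <- stats::quantile(F[pos], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    # boundary ties go down: class k iff value <= q_k
    cls <- 1L + (F[pos] > qs[1]) + (F[pos] > qs[2]) + (F[pos] > qs[3])
    out[pos] <- paste0("Q", cls)
  }
  factor(out, levels = c("C0", "Q1", "Q2", "Q3", "Q4"))
}

#' Write a kinship matrix to file
#'
#' `format = "long"` writes a TSV with columns `id1`, `id2`, `phi` covering
#' the upper triangle including the diagonal; `format = "matrix"` writes the
#' square matrix with an `id` header column.
#'
#' @param kin a `kinship_result`.
#' @param path output file.
#' @param format `"long"` or `"matrix"`.
#' @param zero_omit drop zero entries in long format (default TRUE).
#' @return the path, invisibly.
#' @export
write_kinship <- function(kin, path, format = c("long", "matrix"),
                          zero_omit = TRUE) {
  stopifnot(inherits(kin, "kinship_result"))
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(id = kin$ids, kin$phi, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(kin$phi, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = kin$ids[ut[, 1]], id2 = kin$ids[ut[, 2]],
                     phi = kin$phi[ut])
    if (zero_omit) df <- df[df$phi != 0, ]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Eigendecomposition of the additive relationship matrix
#'
#' One-time symmetric eigendecomposition of \eqn{A = 2\Phi} for a given set of
#' individuals, reused across [polygenic()] fits and phenotype simulations on
#' the same pedigree.  Small negative eigenvalues from floating-point error
#' (above `-1e-8`) are clamped to zero; anything more negative is rejected as
#' a non-positive-semidefinite relatedness matrix.
#'
#' @param kin a `kinship_result`.
#' @param ids optional subset/order of individuals.
#' @return object of class `kinship_eigen`: list with `ids`, `values`,
#'   `vectors` such that `2*phi = vectors %*% diag(values) %*% t(vectors)`.
#' @export
kinship_eigen <- function(kin, ids = NULL) {
  stopifnot(inherits(kin, "kinship_result"))
  if (is.null(ids)) ids <- kin$ids
  missing <- setdiff(ids, kin$ids)
  if (length(missing))
    stop("ids absent from kinship result: ", paste(missing, collapse = ", "))
  A <- 2 * kin$phi[ids, ids, drop = FALSE]
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("relatedness matrix 2*Phi is not positive semidefinite ",
         sprintf("(min eigenvalue %.3g)", min(e$values)))
  e$values[e$values < 0] <- 0
  structure(list(ids = ids, values = e$values, vectors = e$vectors),
            class = "kinship_eigen")
}
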