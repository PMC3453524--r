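## Additive (numerator) relationship matrix and its sparse inverse.

#' Additive genetic relationship matrix from a pedigree
#'
#' Tabular (recursive) method in topological order:
#' \code{a(i,j) = 0.5 * (a(j, sire(i)) + a(j, dam(i)))} for \code{j < i} and
#' \code{a(i,i) = 1 + 0.5 * a(sire(i), dam(i))}; an unknown parent
#' contributes 0. The sparse inverse is assembled simultaneously from
#' Henderson's rules with inbreeding accounted for, using the
#' Mendelian-sampling variances
#' \code{d_i = 0.5 - 0.25 * (F_sire + F_dam)} (both parents known),
#' \code{0.75 - 0.25 * F_parent} (one known) or 1 (founder).
#'
#' @param ped a \code{Pedigree}.
#' @return A \code{\linkS4class{RelationshipMatrix}} holding the dense A,
#'   its sparse inverse and per-animal inbreeding coefficients.
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d"))
#' additiveRelationship(ped)@A["s", "o"]   # 0.5
#' @export
additiveRelationship <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  ids <- ped@animal
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  si <- unname(idx[ped@sire])
  di <- unname(idx[ped@dam])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(s)) v <- v + A[prev, s]
      if (!is.na(d)) v <- v + A[prev, d]
      v <- 0.5 * v
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  Fi <- diag(A) - 1
  ## Henderson/Quaas rules for the inverse (triplets preallocated: an animal
  ## contributes at most 9 entries)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  put <- function(i, j, x) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- x
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dMend <- 1 - 0.25 * (if (!is.na(s)) 1 + Fi[s] else 0) -
                 0.25 * (if (!is.na(d)) 1 + Fi[d] else 0)
    alpha <- 1 / dMend
    par <- c(s, d)
    par <- par[!is.na(par)]
    put(i, i, alpha)
    for (p in par) {
      put(i, p, -alpha / 2)
      put(p, i, -alpha / 2)
    }
    for (p in par) for (q in par) put(p, q, alpha / 4)
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ids, ids))
  Ainv <- methods::as(Ainv, "CsparseMatrix")
  new("RelationshipMatrix", A = A, Ainv = Ainv, animals = ids,
      inbreeding = unname(Fi))
}

#' Sparse inverse of the additive relationship matrix
#'
#' @param ped a \code{Pedigree}.
#' @return A sparse symmetric matrix (\code{dgCMatrix}) in pedigree order,
#'   equal to the inverse of the tabular-method A.
#' @export
relationshipInverse <- function(ped) {
  additiveRelationship(ped)@Ainv
}
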