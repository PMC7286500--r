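# Numerator relationship matrix and status-number effective size.

#' Validate and normalize a pedigree table
#'
#' Checks ids are unique, parents precede their offspring (reordering
#' topologically when possible), and no individual is its own ancestor.
#' Unknown parents are coded `"0"` or `NA`.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return The pedigree, topologically ordered, with `"0"` for unknown.
#' @export
validate_pedigree <- function(ped) {
  if (!is.data.frame(ped) || !all(c("id", "sire", "dam") %in% names(ped))) {
    stop("pedigree must be a data.frame with columns id, sire, dam",
         call. = FALSE)
  }
  if (nrow(ped) == 0L) stop("pedigree has no records", call. = FALSE)
  ped <- data.frame(id = as.character(ped$id), sire = as.character(ped$sire),
                    dam = as.character(ped$dam), stringsAsFactors = FALSE)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  if (anyDuplicated(ped$id)) {
    stop(sprintf("duplicate pedigree id: %s",
                 ped$id[duplicated(ped$id)][1L]), call. = FALSE)
  }
  known <- setdiff(unique(c(ped$sire, ped$dam)), c("0", ped$id))
  if (length(known)) {
    stop(sprintf("parent '%s' never appears as an individual", known[1L]),
         call. = FALSE)
  }
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  # already parents-first? keep the given order untouched
  sire_pos <- ifelse(ped$sire == "0", 0L, pos[ped$sire])
  dam_pos <- ifelse(ped$dam == "0", 0L, pos[ped$dam])
  if (all(sire_pos < pos) && all(dam_pos < pos)) {
    return(ped)
  }
  # otherwise Kahn-style topological reordering (level order)
  placed <- logical(nrow(ped))
  order_out <- integer(0)
  remaining <- seq_len(nrow(ped))
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      s <- ped$sire[i]; d <- ped$dam[i]
      (s == "0" || placed[pos[[s]]]) && (d == "0" || placed[pos[[d]]])
    }, logical(1))]
    if (!length(ready)) {
      if (length(remaining)) {
        stop(sprintf("pedigree cycle involving id '%s'",
                     ped$id[remaining[1L]]), call. = FALSE)
      }
      break
    }
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Numerator relationship matrix from a pedigree
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' recursive method: processing individuals parents-first,
#' `a_ij = 0.5 * (a_{i,sire(j)} + a_{i,dam(j)})` for earlier `i`, and
#' `a_jj = 1 + 0.5 * a_{sire(j),dam(j)}`; an unknown parent contributes
#' zero relationship. Unknown parents are thereby treated as unique,
#' unrelated, non-inbred founders. The diagonal equals `1 + F`, twice the
#' self-kinship.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`; `"0"`/`NA`
#'   unknown); reordered via [validate_pedigree()] if needed.
#' @return Dense symmetric matrix with ids as dimnames.
#' @examples
#' trio <- data.frame(id = c("p1", "p2", "o"),
#'                    sire = c("0", "0", "p1"), dam = c("0", "0", "p2"))
#' build_numerator_relationship(trio)
#' @export
build_numerator_relationship <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in idx) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      rel <- 0.5 * ((if (s > 0L) A[prev, s] else 0) +
                    (if (d > 0L) A[prev, d] else 0))
      A[prev, j] <- rel
      A[j, prev] <- rel
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients from a relationship matrix
#'
#' @param A numerator relationship matrix from
#'   [build_numerator_relationship()].
#' @return Named vector `F = diag(A) - 1`.
#' @export
inbreeding_coefficients <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  diag(A) - 1
}

#' Proportional gene contributions to a set of individuals
#'
#' Traces each target individual's genome back through the pedigree:
#' every individual owes half its genes to each parent, and an unknown
#' parent is that individual's own unique phantom founder. The returned
#' vector averages these shares over the targets, giving each pedigree
#' member's expected proportional contribution to the target gene pool
#' (non-zero only for founders and phantom-parent carriers).
#'
#' @param ped pedigree data.frame.
#' @param individuals character ids of the target group (e.g. the
#'   planted offspring); defaults to every pedigree member not recorded
#'   as a parent.
#' @return Named numeric vector over pedigree ids, summing to 1; phantom
#'   contributions from unknown parents are credited to the individual
#'   carrying them under the name `<id>/unknown`.
#' @export
founder_contributions <- function(ped, individuals = NULL) {
  ped <- validate_pedigree(ped)
  if (is.null(individuals)) {
    individuals <- setdiff(ped$id, c(ped$sire, ped$dam))
  }
  if (!all(individuals %in% ped$id)) {
    stop("some target individuals are not in the pedigree", call. = FALSE)
  }
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  founder <- ped$sire == "0" & ped$dam == "0"
  # gene shares flow to parents linearly, so one reverse topological pass
  # pushes all targets' mass to founders/phantoms simultaneously
  w <- numeric(n)
  w[idx[individuals]] <- 1 / length(individuals)
  phantom <- numeric(n)                 # unknown-parent share carried by row
  for (j in rev(idx)) {
    if (w[j] == 0 || founder[j]) next
    s <- ped$sire[j]; d <- ped$dam[j]
    if (s == "0") phantom[j] <- phantom[j] + 0.5 * w[j]
    else w[idx[[s]]] <- w[idx[[s]]] + 0.5 * w[j]
    if (d == "0") phantom[j] <- phantom[j] + 0.5 * w[j]
    else w[idx[[d]]] <- w[idx[[d]]] + 0.5 * w[j]
    w[j] <- 0
  }
  out <- w
  names(out) <- ped$id
  ph <- phantom
  if (any(ph > 0)) {
    extra <- ph[ph > 0]
    names(extra) <- paste0(ped$id[ph > 0], "/unknown")
    out <- c(out, extra)
  }
  out
}

#' Status-number effective population size
#'
#' The status number Ns is half the inverse of the group coancestry of a
#' gene pool under given parental contributions:
#' `Theta = c' (A/2) c` and `Ns = 0.5 / Theta = 1 / (c' A c)`. For equal
#' contributions from N unrelated, non-inbred founders, `Ns = N`; any
#' imbalance or relatedness lowers it.
#'
#' @param A relationship matrix (or identity behaviour via
#'   `A = NULL` for unrelated non-inbred contributors).
#' @param contributions numeric contribution vector, non-negative and
#'   summing to 1. If named and `A` has dimnames, matched by name;
#'   contributors absent from `A` (e.g. phantom founders) are taken as
#'   unrelated and non-inbred.
#' @return The effective number Ns.
#' @export
status_number <- function(A, contributions) {
  if (length(contributions) == 0L) {
    stop("empty contribution vector", call. = FALSE)
  }
  if (any(contributions < -1e-12)) {
    stop("contributions must be non-negative", call. = FALSE)
  }
  s <- sum(contributions)
  if (abs(s - 1) > 1e-8) {
    stop("contributions must sum to 1", call. = FALSE)
  }
  if (is.null(A)) {
    theta <- 0.5 * sum(contributions^2)
  } else {
    stopifnot(is.matrix(A))
    cin <- contributions
    extra <- 0
    if (!is.null(names(cin)) && !is.null(rownames(A))) {
      inA <- names(cin) %in% rownames(A)
      extra <- sum(cin[!inA]^2)          # unrelated non-inbred outsiders
      cA <- cin[inA]
      theta <- 0.5 * (drop(cA %*% A[names(cA), names(cA)] %*% cA) + extra)
    } else {
      if (length(cin) != nrow(A)) {
        stop("contribution vector does not match A", call. = FALSE)
      }
      theta <- 0.5 * drop(cin %*% A %*% cin)
    }
  }
  0.5 / theta
}

#' Status number of a simulated trial's planted crop
#'
#' Convenience wrapper: contributions of pedigree founders (and phantom
#' unknown parents) to the trial offspring, combined with the pedigree
#' relationship matrix.
#'
#' @param ped pedigree data.frame.
#' @param individuals target ids; default the non-parent individuals.
#' @return Ns for the target gene pool.
#' @export
status_number_pedigree <- function(ped, individuals = NULL) {
  ped <- validate_pedigree(ped)
  contrib <- founder_contributions(ped, individuals)
  contrib <- contrib[contrib > 0]
  A <- build_numerator_relationship(ped)
  status_number(A, contrib)
}
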