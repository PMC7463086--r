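#' Build a validated, topologically ordered pedigree
#'
#' Takes animal/sire/dam trios (text IDs; `"0"`, `""` or `NA` mark an unknown
#' parent), checks them, appends parents that never occur as animals as
#' founder records, and reorders the records so that every parent precedes
#' its offspring. Ordering is stable: among animals whose parents are already
#' placed, the original input order is kept. Inbreeding coefficients are
#' computed on construction with the Meuwissen-Luo algorithm.
#'
#' @param animal,sire,dam character vectors of equal length, or `animal` may
#'   be a data.frame whose first three columns are animal, sire, dam.
#' @return An object of class `pedigree`: a list with elements
#'   \describe{
#'     \item{id}{character vector of animal IDs in sorted order}
#'     \item{sire,dam}{integer indices into `id` (0 = unknown)}
#'     \item{F}{per-animal inbreeding coefficient}
#'     \item{d}{Mendelian-sampling variance used by [nrm_inverse()]}
#'     \item{input_order}{position of each sorted record in the input}
#'   }
#' @examples
#' ped <- pedigree(c("s", "d", "x"), c("0", "0", "s"), c("0", "0", "d"))
#' ped$F
#' @export
pedigree <- function(animal, sire = NULL, dam = NULL) {
  if (is.data.frame(animal)) {
    stopifnot(ncol(animal) >= 3)
    sire <- as.character(animal[[2]])
    dam <- as.character(animal[[3]])
    animal <- as.character(animal[[1]])
  }
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(animal) == 0) stop("pedigree is empty")
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  unk <- function(x) is.na(x) | x == "0" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (any(unk(animal))) stop("animal IDs must be non-empty and not the unknown sentinel")
  if (anyDuplicated(animal)) {
    stop("duplicate animal ID(s): ",
         paste(unique(animal[duplicated(animal)])[1:min(3, sum(duplicated(animal)))],
               collapse = ", "))
  }
  # parents never listed as animals become founder records (prepended so the
  # stable topological sort can place them before their offspring)
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  extra <- setdiff(parents, animal)
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
  }
  n <- length(animal)
  idx <- match(animal, animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  # stable Kahn-style topological sort: repeated passes in input order
  placed <- logical(n)
  order_out <- integer(n)
  k <- 0L
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      (si[i] == 0L || placed[si[i]]) && (di[i] == 0L || placed[di[i]])
    }, logical(1))
    if (!any(ready)) {
      cyc <- find_cycle_member(remaining, si, di)
      stop("pedigree contains a cycle involving animal '", animal[cyc], "'")
    }
    sel <- remaining[ready]
    order_out[k + seq_along(sel)] <- sel
    k <- k + length(sel)
    placed[sel] <- TRUE
    remaining <- remaining[!ready]
  }

  pos <- integer(n)
  pos[order_out] <- seq_len(n)
  id <- animal[order_out]
  s2 <- si[order_out]
  d2 <- di[order_out]
  s2[s2 > 0L] <- pos[s2[s2 > 0L]]
  d2[d2 > 0L] <- pos[d2[d2 > 0L]]

  ml <- meuwissen_luo(s2, d2)
  structure(
    list(id = id, sire = s2, dam = d2, F = ml$F, d = ml$d,
         input_order = order_out),
    class = "pedigree"
  )
}

# locate one member of a cycle among unplaced records (each remaining record
# has at least one remaining ancestor, so following parents must loop)
find_cycle_member <- function(remaining, si, di) {
  in_rem <- logical(length(si))
  in_rem[remaining] <- TRUE
  cur <- remaining[1]
  seen <- integer(0)
  repeat {
    if (cur %in% seen) return(cur)
    seen <- c(seen, cur)
    nxt <- c(si[cur], di[cur])
    nxt <- nxt[nxt > 0L & in_rem[pmax(nxt, 1L)]]
    if (!length(nxt)) return(cur) # blocked but not a self-loop: report anyway
    cur <- nxt[1]
  }
}

# Meuwissen & Luo (1992) inbreeding with Henderson's Mendelian-sampling
# variances. sire/dam are indices into the sorted order (0 = unknown).
# Convention: F = 0 whenever either parent is unknown.
meuwissen_luo <- function(sire, dam) {
  n <- length(sire)
  Fcoef <- numeric(n)
  d <- numeric(n)
  w <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; dd <- dam[i]
    if (s == 0L && dd == 0L) {
      d[i] <- 1
    } else if (s == 0L || dd == 0L) {
      d[i] <- 0.75 - 0.25 * Fcoef[max(s, dd)]
    } else {
      d[i] <- 0.5 - 0.25 * (Fcoef[s] + Fcoef[dd])
      # F_i = sum over ancestors j (incl. i) of L_ij^2 d_j, minus 1
      anc <- i
      stack <- i
      seenv <- rep(FALSE, i)
      seenv[i] <- TRUE
      while (length(stack)) {
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        for (p in c(sire[j], dam[j])) {
          if (p > 0L && !seenv[p]) {
            seenv[p] <- TRUE
            anc <- c(anc, p)
            stack <- c(stack, p)
          }
        }
      }
      anc <- sort(anc, decreasing = TRUE)
      w[anc] <- 0
      w[i] <- 1
      fi <- -1
      for (j in anc) {
        wj <- w[j]
        if (wj == 0) next
        sj <- sire[j]; dj <- dam[j]
        if (sj > 0L) w[sj] <- w[sj] + 0.5 * wj
        if (dj > 0L) w[dj] <- w[dj] + 0.5 * wj
        fi <- fi + wj * wj * d[j]
      }
      Fcoef[i] <- fi
    }
  }
  list(F = Fcoef, d = d)
}

#' Inbreeding coefficients of a pedigree
#'
#' Meuwissen-Luo inbreeding coefficients, computed at construction time.
#' Animals with any unknown parent have F = 0 under the unrelated-founder
#' convention for unknown parents.
#'
#' @param ped a [pedigree()] object.
#' @return Named numeric vector of F in `[0, 1)`, in sorted pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  stats::setNames(ped$F, ped$id)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' recursion: `A[i,i] = 1 + F_i` and `A[i,j] = 0.5 (A[j,s_i] + A[j,d_i])`,
#' with unknown parents contributing zero. Dense; intended for desk-scale
#' pedigrees (up to a few thousand animals).
#'
#' @param ped a [pedigree()] object.
#' @param ids optional character vector of animal IDs: return only that
#'   subset of rows/columns (e.g. A22 over genotyped animals).
#' @return Symmetric numeric matrix with animal IDs as dimnames.
#' @export
nrm <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  A <- matrix(0, n, n)
  sire <- ped$sire; dam <- ped$dam
  for (i in seq_len(n)) {
    s <- sire[i]; dd <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s > 0L) v <- v + 0.5 * A[j, s]
      if (dd > 0L) v <- v + 0.5 * A[j, dd]
      A[i, j] <- v
      A[j, i] <- v
    }
    A[i, i] <- 1 + (if (s > 0L && dd > 0L) 0.5 * A[s, dd] else 0)
  }
  dimnames(A) <- list(ped$id, ped$id)
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped$id)
    if (length(miss)) stop("IDs not in pedigree: ", paste(utils::head(miss, 3), collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes `1/d_i` to
#' (i,i), `-1/(2 d_i)` to (i, parent), and `1/(4 d_i)` to the parent block,
#' where `d_i` is the Mendelian-sampling variance computed from parental
#' inbreeding (`0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_known` with one, 1 with none).
#'
#' @param ped a [pedigree()] object.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) over all pedigree
#'   animals, with IDs as dimnames.
#' @export
nrm_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  s <- ped$sire; dd <- ped$dam
  inv_d <- 1 / ped$d
  i0 <- seq_len(n)
  ii <- i0; jj <- i0; xx <- inv_d
  hs <- s > 0L
  hd <- dd > 0L
  # animal-parent cross terms (both triangles; duplicates are summed)
  ii <- c(ii, i0[hs], s[hs], i0[hd], dd[hd])
  jj <- c(jj, s[hs], i0[hs], dd[hd], i0[hd])
  xx <- c(xx, rep(-0.5 * inv_d[hs], 2), rep(-0.5 * inv_d[hd], 2))
  # parent-parent terms
  ii <- c(ii, s[hs], dd[hd])
  jj <- c(jj, s[hs], dd[hd])
  xx <- c(xx, 0.25 * inv_d[hs], 0.25 * inv_d[hd])
  both <- hs & hd
  ii <- c(ii, s[both], dd[both])
  jj <- c(jj, dd[both], s[both])
  xx <- c(xx, rep(0.25 * inv_d[both], 2))
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Average pedigree relatedness
#'
#' Mean off-diagonal relationship of each animal's row of A: how related an
#' animal is, on average, to the rest of the matrix. A singleton matrix
#' returns 0 by convention.
#'
#' @param A numerator relationship matrix from [nrm()].
#' @param ids animal IDs to report (default: all rows of `A`).
#' @return Named numeric vector of row means excluding the diagonal.
#' @export
mean_relatedness <- function(A, ids = rownames(A)) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (is.null(rownames(A))) stop("A must carry animal IDs as dimnames")
  miss <- setdiff(ids, rownames(A))
  if (length(miss)) stop("IDs not in A: ", paste(utils::head(miss, 3), collapse = ", "))
  n <- nrow(A)
  if (n == 1L) return(stats::setNames(0, rownames(A))[ids])
  out <- (rowSums(A) - diag(A)) / (n - 1)
  out[ids]
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", length(x$id), "animals,",
      sum(x$sire == 0L & x$dam == 0L), "founders\n")
  cat("Mean inbreeding F:", signif(mean(x$F), 3),
      "| inbred animals:", sum(x$F > 0), "\n")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(
    animal = x$id,
    sire = ifelse(x$sire > 0L, x$id[pmax(x$sire, 1L)], "0"),
    dam = ifelse(x$dam > 0L, x$id[pmax(x$dam, 1L)], "0"),
    order = seq_along(x$id),
    F = x$F,
    stringsAsFactors = FALSE
  )
}

#' Read a pedigree CSV
#'
#' Expects header `animal,sire,dam`; `"0"` or empty marks an unknown parent.
#'
#' @param path file path.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns animal, sire, dam")
  pedigree(df$animal, df$sire, df$dam)
}

#' Write a sorted pedigree CSV
#'
#' Emits the sorted pedigree with added columns `order` and `F`.
#'
#' @param ped a [pedigree()] object.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
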