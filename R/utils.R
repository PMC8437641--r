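clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))
}

as_binary <- function(x) {
  storage.mode(x) <- "double"
  x
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Label 8-connected components of a binary mask
#'
#' Components are first labeled with 4-connectivity and labels touching
#' diagonally are then merged (union-find), which yields exact 8-connected
#' components. Labels are renumbered 1..K in raster order of first
#' occurrence.
#'
#' @param mask binary matrix (0/1 or logical).
#' @return integer matrix of the same shape; 0 is background.
#' @keywords internal
label8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  k <- max(lab)
  if (k <= 1L) return(lab)
  # diagonal adjacencies between distinct 4-connected labels
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  # renumber roots consecutively in first-occurrence (column-major) order
  uniq <- unique(root[lab[lab > 0L]])
  remap <- match(root, uniq)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_mat <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

NEIGH8 <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# reflect-pad a matrix by (pr, pc) on each side
pad_reflect <- function(x, pr, pc) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(pr < nr, pc < nc)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  x[ri, ci]
}
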