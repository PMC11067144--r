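#' Top-k brightest connected-voxel selection
#'
#' Implements the LC area search: a deterministic greedy construction
#' seeded at the maximum-intensity voxel of the box, repeatedly adding the
#' highest-intensity voxel that is lattice-adjacent (under the chosen
#' connectivity) to the current set and inside the box, stopping when the
#' set holds \code{k} voxels or no adjacent candidate remains. Ties are
#' broken by the smallest linearized voxel index (x fastest, then y, then
#' z), which makes the search fully deterministic.
#'
#' @param image an \code{image_volume}.
#' @param box n x 3 integer matrix of voxel indices defining the search
#'   region.
#' @param k number of voxels to select (default 10).
#' @param connectivity lattice connectivity: 6, 18 or 26 (default 26).
#' @return an m x 3 integer matrix of selected voxels in selection order
#'   (m <= k; m < k only when the connected frontier is exhausted, which
#'   is reported downstream as a QC condition, not an error).
#' @export
select_brightest_connected <- function(image, box, k = 10L,
                                       connectivity = 26L) {
  stopifnot(inherits(image, "image_volume"))
  box <- matrix(as.integer(box), ncol = 3L)
  if (nrow(box) < 1L) stop("search box is empty", call. = FALSE)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  dimg <- dim(image$data)
  vals <- image$data[.linear_index(box, dimg)]
  if (any(!is.finite(vals)))
    stop("non-finite intensities inside the search box", call. = FALSE)

  n <- nrow(box)
  lin <- .linear_index(box, dimg)
  # position-in-box lookup over the image grid
  pos <- array(0L, dimg)
  pos[lin] <- seq_len(n)
  off <- .connectivity_offsets(as.integer(connectivity))

  in_set <- logical(n)
  candidate <- logical(n)
  seed <- order(-vals, lin)[1L]
  selected <- integer(0)
  current <- seed
  repeat {
    in_set[current] <- TRUE
    candidate[current] <- FALSE
    selected <- c(selected, current)
    if (length(selected) == k) break
    nb <- sweep(off, 2L, box[current, ], `+`)
    ok <- nb[, 1L] >= 1 & nb[, 1L] <= dimg[1L] &
      nb[, 2L] >= 1 & nb[, 2L] <= dimg[2L] &
      nb[, 3L] >= 1 & nb[, 3L] <= dimg[3L]
    if (any(ok)) {
      p <- pos[.linear_index(nb[ok, , drop = FALSE], dimg)]
      p <- p[p > 0L]
      candidate[p[!in_set[p]]] <- TRUE
    }
    cand <- which(candidate)
    if (length(cand) == 0L) break
    current <- cand[order(-vals[cand], lin[cand])[1L]]
  }
  box[selected, , drop = FALSE]
}

#' Exact maximum-sum connected k-subset (slow reference mode)
#'
#' Enumerates all connected voxel subsets of size \code{k} inside the box
#' and returns the one with the largest intensity sum (ties broken by the
#' lexicographically smallest sorted linear-index vector). The exact
#' search is exponential and intended only for very small boxes and
#' \code{k <= 6}; the greedy rule in
#' \code{\link{select_brightest_connected}} is the production path.
#'
#' @inheritParams select_brightest_connected
#' @param max_subsets safety cap on the number of enumerated subsets.
#' @return an k x 3 integer matrix, or NULL if no connected subset of
#'   size k exists.
#' @export
select_brightest_connected_exact <- function(image, box, k = 4L,
                                             connectivity = 26L,
                                             max_subsets = 2e6) {
  stopifnot(inherits(image, "image_volume"))
  box <- matrix(as.integer(box), ncol = 3L)
  if (k > 6L) stop("exact mode supports k <= 6 only", call. = FALSE)
  dimg <- dim(image$data)
  n <- nrow(box)
  vals <- image$data[.linear_index(box, dimg)]
  pos <- array(0L, dimg)
  pos[.linear_index(box, dimg)] <- seq_len(n)
  off <- .connectivity_offsets(as.integer(connectivity))
  # adjacency lists within the box
  adj <- lapply(seq_len(n), function(i) {
    nb <- sweep(off, 2L, box[i, ], `+`)
    ok <- nb[, 1L] >= 1 & nb[, 1L] <= dimg[1L] &
      nb[, 2L] >= 1 & nb[, 2L] <= dimg[2L] &
      nb[, 3L] >= 1 & nb[, 3L] <= dimg[3L]
    p <- pos[.linear_index(nb[ok, , drop = FALSE], dimg)]
    sort(p[p > 0L])
  })

  best_sum <- -Inf
  best <- NULL
  count <- 0L
  # enumerate connected subsets with fixed root = smallest member, so each
  # subset is produced exactly once
  grow <- function(members, frontier, root) {
    if (length(members) == k) {
      count <<- count + 1L
      if (count > max_subsets)
        stop("exact search exceeded `max_subsets`", call. = FALSE)
      s <- sum(vals[members])
      # ties keep the first subset in enumeration order, which is the
      # lexicographically smallest by construction of the root loop
      if (s > best_sum + 1e-12) {
        best_sum <<- s
        best <<- members
      }
      return(invisible())
    }
    frontier <- frontier[frontier > root]
    while (length(frontier) > 0L) {
      v <- frontier[1L]
      frontier <- frontier[-1L]
      new_frontier <- union(frontier, setdiff(adj[[v]], c(members, v)))
      grow(c(members, v), new_frontier, root)
    }
  }
  for (root in seq_len(n)) grow(root, adj[[root]], root)
  if (is.null(best)) return(NULL)
  box[best, , drop = FALSE]
}

# BFS connectivity check of a voxel set
.is_connected <- function(vox, connectivity = 26L) {
  n <- nrow(vox)
  if (n <= 1L) return(n == 1L)
  off <- .connectivity_offsets(as.integer(connectivity))
  key <- paste(vox[, 1L], vox[, 2L], vox[, 3L])
  idx <- seq_len(n)
  names(idx) <- key
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- sweep(off, 2L, vox[v, ], `+`)
    hit <- idx[paste(nb[, 1L], nb[, 2L], nb[, 3L])]
    hit <- hit[!is.na(hit)]
    new <- hit[!seen[hit]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

.side_qc <- function(selected, box, k, connectivity) {
  box_key <- paste(box[, 1L], box[, 2L], box[, 3L])
  sel_key <- paste(selected[, 1L], selected[, 2L], selected[, 3L])
  centroid <- round(colMeans(selected))
  list(size = nrow(selected),
       size_ok = nrow(selected) == k,
       connected = .is_connected(selected, connectivity),
       inside_box = all(sel_key %in% box_key),
       centroid_in_box = paste(centroid[1L], centroid[2L], centroid[3L])
         %in% box_key)
}

#' Compute the locus coeruleus signal intensity (LC-I)
#'
#' Runs the brightest-connected-voxel search in the left and right LC
#' boxes, normalizes each side's mean intensity by the mean intensity of
#' the pontomesencephalic reference box, and averages the two sides. Two
#' normalization formulas are provided: \code{"ratio"} (default) gives
#' \code{m / r} and \code{"contrast"} gives \code{(m - r) / r}, where
#' \code{m} is the selected-set mean and \code{r} the reference mean.
#' Both are invariant under global multiplicative rescaling of the image.
#'
#' A side whose selected set fails QC (wrong size, disconnected, or
#' outside its box) is excluded from the side average and flagged; no
#' voxel is ever modified.
#'
#' @param image an \code{image_volume} in native space.
#' @param native_boxes a native-space \code{box_set} on the image grid.
#' @param k number of voxels per side (default 10).
#' @param connectivity lattice connectivity (default 26).
#' @param formula \code{"ratio"} or \code{"contrast"}.
#' @return an object of class \code{lc_result} with elements
#'   \code{selected_left}, \code{selected_right}, \code{lc_i_left},
#'   \code{lc_i_right}, \code{lc_i}, \code{reference_mean} and \code{qc}.
#' @export
compute_lc_intensity <- function(image, native_boxes, k = 10L,
                                 connectivity = 26L,
                                 formula = c("ratio", "contrast")) {
  stopifnot(inherits(image, "image_volume"), inherits(native_boxes, "box_set"))
  formula <- match.arg(formula)
  dimg <- dim(image$data)
  if (!all(native_boxes$grid_dim == dimg))
    stop("boxes are not on the image grid (", paste(native_boxes$grid_dim,
         collapse = "x"), " vs ", paste(dimg, collapse = "x"), ")",
         call. = FALSE)
  ref_vals <- image$data[.linear_index(native_boxes$boxes$reference, dimg)]
  if (any(!is.finite(ref_vals)))
    stop("non-finite intensities in the reference box", call. = FALSE)
  r <- mean(ref_vals)
  if (r <= 0)
    stop("reference mean is <= 0; normalization is corrupted", call. = FALSE)

  norm <- function(m) if (formula == "ratio") m / r else (m - r) / r
  side <- function(name) {
    box <- native_boxes$boxes[[name]]
    sel <- select_brightest_connected(image, box, k = k,
                                      connectivity = connectivity)
    qc <- .side_qc(sel, box, k, connectivity)
    m <- mean(image$data[.linear_index(sel, dimg)])
    list(selected = sel, lc_i = norm(m), qc = qc,
         valid = qc$size_ok && qc$connected && qc$inside_box)
  }
  left <- side("lc_left")
  right <- side("lc_right")
  vals <- c(if (left$valid) left$lc_i, if (right$valid) right$lc_i)
  structure(list(selected_left = left$selected,
                 selected_right = right$selected,
                 lc_i_left = left$lc_i, lc_i_right = right$lc_i,
                 lc_i = if (length(vals)) mean(vals) else NA_real_,
                 reference_mean = r, formula = formula, k = as.integer(k),
                 qc = list(left = left$qc, right = right$qc,
                           left_valid = left$valid,
                           right_valid = right$valid)),
            class = "lc_result")
}

#' @export
print.lc_result <- function(x, ...) {
  cat(sprintf("<lc_result> LC-I (%s) = %.4f  [left %.4f%s, right %.4f%s]\n",
              x$formula, x$lc_i, x$lc_i_left,
              if (x$qc$left_valid) "" else " QC-FAIL", x$lc_i_right,
              if (x$qc$right_valid) "" else " QC-FAIL"))
  invisible(x)
}
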