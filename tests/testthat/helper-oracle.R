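# Independent re-derivation of the brightest-connected selection rule,
# written directly from its verbal description and sharing no code with
# the package implementation: start from the brightest voxel of the box
# (ties: smallest linearized index, x fastest); at every step list all
# box voxels adjacent to the current set and take the brightest of them
# (same tie rule); stop at k voxels or when no adjacent voxel remains.
# The set, not the order, is the contract.
oracle_brightest_connected <- function(arr, box, k, connectivity = 26) {
  dims <- dim(arr)
  box <- as.matrix(box)
  lin <- (box[, 3] - 1) * dims[1] * dims[2] + (box[, 2] - 1) * dims[1] +
    box[, 1]
  vals <- arr[lin]
  n <- nrow(box)
  in_set <- rep(FALSE, n)
  in_set[order(-vals, lin)[1]] <- TRUE
  while (sum(in_set) < k) {
    members <- box[in_set, , drop = FALSE]
    rest <- which(!in_set)
    if (!length(rest)) break
    dx <- abs(outer(box[rest, 1], members[, 1], "-"))
    dy <- abs(outer(box[rest, 2], members[, 2], "-"))
    dz <- abs(outer(box[rest, 3], members[, 3], "-"))
    cheb <- pmax(dx, dy, dz)
    manh <- dx + dy + dz
    adj_mat <- switch(as.character(connectivity),
                      "6" = manh == 1,
                      "18" = cheb == 1 & manh <= 2,
                      "26" = cheb == 1)
    cand <- rest[rowSums(adj_mat) > 0]
    if (!length(cand)) break
    in_set[cand[order(-vals[cand], lin[cand])[1]]] <- TRUE
  }
  sort(lin[in_set])
}

# linear indices (x fastest) of a voxel matrix, for set comparisons
lin_of <- function(vox, dims) {
  sort((vox[, 3] - 1) * dims[1] * dims[2] + (vox[, 2] - 1) * dims[1] +
         vox[, 1])
}
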