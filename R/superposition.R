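# Rigid-body superposition of paired CA coordinate sets (Kabsch, reflections
# excluded) with iterative pruning of poorly fitting pairs: the RMSD is
# reported over the kept pairs, the way "pruned atom pairs" RMSDs are.

#' Construct a CA coordinate set
#'
#' @param coords n x 3 numeric matrix of coordinates in Angstrom.
#' @param labels Residue labels (defaults to row numbers).
#' @return A `coordinate_set`.
#' @export
coordinate_set <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 3L, all(is.finite(coords)))
  if (is.null(labels)) labels <- as.character(seq_len(nrow(coords)))
  stopifnot(length(labels) == nrow(coords))
  structure(list(labels = as.character(labels), coords = coords),
            class = "coordinate_set")
}

as_coordinate_set <- function(x) {
  if (inherits(x, "coordinate_set")) x else coordinate_set(x)
}

#' Least-squares superposition (Kabsch)
#'
#' Optimal rotation and translation mapping `X` onto `Y` (pairs matched by
#' index), with reflections excluded; returns the RMSD over all pairs.
#'
#' @param X,Y [coordinate_set()]s (or n x 3 matrices) of equal size.
#' @return A `superposition_result`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd`, `kept_pairs`, `pruned_labels`.
#' @export
kabsch <- function(X, Y) {
  X <- as_coordinate_set(X); Y <- as_coordinate_set(Y)
  if (nrow(X$coords) != nrow(Y$coords))
    stop("coordinate sets differ in size")
  n <- nrow(X$coords)
  if (n < 3L) stop("need at least 3 paired points")
  cx <- colMeans(X$coords); cy <- colMeans(Y$coords)
  Xc <- sweep(X$coords, 2, cx); Yc <- sweep(Y$coords, 2, cy)
  if (svd(Xc)$d[2] < 1e-9 || svd(Yc)$d[2] < 1e-9)
    warning("degenerate (collinear) coordinate set; rotation ill-determined")
  H <- t(Xc) %*% Yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cy - R %*% cx),
                 rmsd = rmsd, kept_pairs = n,
                 pruned_labels = character(),
                 labels = X$labels),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d pairs (%d pruned)\n",
              x$rmsd, x$kept_pairs, length(x$pruned_labels)))
  invisible(x)
}

#' Apply a superposition transform
#'
#' @param result A [kabsch()] / [prune_superpose()] result.
#' @param coords n x 3 matrix (or [coordinate_set()]).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(result, coords) {
  coords <- as_coordinate_set(coords)$coords
  sweep(coords %*% t(result$rotation), 2, result$translation, `+`)
}

#' Superposition with iterative pair pruning
#'
#' Repeats: superpose the kept pairs, then drop every pair whose residual
#' distance exceeds `cutoff`; stops when no pair is dropped, `max_iter` is
#' reached, or pruning would leave fewer than 3 pairs (then stops with a
#' warning instead of pruning). The RMSD is over the kept ("pruned atom
#' pairs") set.
#'
#' @param X,Y Paired [coordinate_set()]s, n >= 4.
#' @param cutoff Residual distance cutoff in Angstrom (default 2.0).
#' @param max_iter Maximum pruning iterations (default 20).
#' @return A `superposition_result` with `kept_pairs`, `pruned_labels` and
#'   the per-iteration `rmsd_trace`.
#' @export
prune_superpose <- function(X, Y, cutoff = 2.0, max_iter = 20L) {
  X <- as_coordinate_set(X); Y <- as_coordinate_set(Y)
  stopifnot(nrow(X$coords) == nrow(Y$coords), nrow(X$coords) >= 4L)
  keep <- rep(TRUE, nrow(X$coords))
  trace <- numeric()
  res <- NULL
  for (iter in seq_len(max_iter)) {
    res <- kabsch(coordinate_set(X$coords[keep, , drop = FALSE],
                                 X$labels[keep]),
                  coordinate_set(Y$coords[keep, , drop = FALSE],
                                 Y$labels[keep]))
    trace <- c(trace, res$rmsd)
    fitted <- apply_transform(res, X$coords[keep, , drop = FALSE])
    dist <- sqrt(rowSums((fitted - Y$coords[keep, , drop = FALSE])^2))
    drop <- dist > cutoff
    if (!any(drop)) break
    if (sum(keep) - sum(drop) < 3L) {
      warning("pruning stopped: fewer than 3 pairs would remain")
      break
    }
    keep[which(keep)[drop]] <- FALSE
  }
  res$kept_pairs <- sum(keep)
  res$pruned_labels <- X$labels[!keep]
  res$rmsd_trace <- trace
  res
}

#' Read CA coordinates of one chain from a PDB file
#'
#' CA atoms in residue order; where alternate locations exist, altloc A is
#' taken. Insertion codes are preserved in the labels.
#'
#' @param pdb PDB file path.
#' @param chain Chain identifier.
#' @return A [coordinate_set()] with labels `"<resno><icode>"`.
#' @export
read_ca_coords <- function(pdb, chain) {
  p <- bio3d::read.pdb(pdb)
  atoms <- p$atom
  chains <- unique(atoms$chain)
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available: ",
         paste(chains, collapse = ", "))
  sel <- atoms$elety == "CA" & atoms$chain == chain &
    (is.na(atoms$alt) | atoms$alt %in% c("", "A"))
  atoms <- atoms[sel, , drop = FALSE]
  icode <- ifelse(is.na(atoms$insert), "", atoms$insert)
  coordinate_set(cbind(atoms$x, atoms$y, atoms$z),
                 paste0(atoms$resno, icode))
}

#' Write a superposition result as JSON
#'
#' @param result A `superposition_result`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_superposition_json <- function(result, path) {
  jsonlite::write_json(
    list(rotation = result$rotation, translation = result$translation,
         rmsd = result$rmsd, kept_pairs = result$kept_pairs,
         pruned_labels = result$pruned_labels),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
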