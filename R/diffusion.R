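## Diffusion map, diffusion pseudotime and tercile sub-populations.
##
## The map is built from a Gaussian kernel on Euclidean distances in the
## (informed) gene space with anisotropic density normalisation (alpha = 1):
## W = K / (q q^T) with q the kernel row sums, then row-normalised to the
## transition matrix T.  Diffusion time is the accumulated-transition
## distance: with the stationary component removed, M = (I - Ttilde)^-1 - I
## and tau_i is the Euclidean distance between rows M[root, ] and M[i, ].

#' Build a diffusion map
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values, typically
#'   restricted to the informed gene set (`x[genes, ]`).
#' @param nComponents number of non-trivial diffusion components to keep.
#' @param kernel `"local_knn"` (default): per-cell kernel scales equal to
#'   the distance to the `knn`-th neighbour (robust to density variation);
#'   `"global_sigma"`: one global scale, the median of those distances.
#' @param knn neighbour index used for the kernel scale.
#' @return a [DiffusionState-class] holding the transition matrix,
#'   eigenvalues and eigenvector components (`DC1..DCk`, eigenvector
#'   scaled by eigenvalue).
#' @export
diffusionMap <- function(x, nComponents = 10L,
                         kernel = c("local_knn", "global_sigma"),
                         knn = 30L) {
  kernel <- match.arg(kernel)
  n <- ncol(x)
  if (n < nComponents + 2L)
    stop("need at least nComponents + 2 cells")
  knn <- min(as.integer(knn), n - 1L)
  d2 <- as.matrix(dist(t(assay(x))))^2
  ## per-cell scale: squared distance to the knn-th neighbour
  nnD2 <- apply(d2, 1, function(r) sort(r)[knn + 1L])
  sigma2 <- switch(kernel,
    local_knn = sqrt(outer(nnD2, nnD2)),
    global_sigma = matrix(median(nnD2), n, n))
  sigma2[sigma2 < 1e-300] <- 1e-300
  K <- exp(-d2 / (2 * sigma2))
  ## anisotropic density normalisation, alpha = 1
  q <- rowSums(K)
  W <- K / outer(q, q)
  dW <- rowSums(W)
  if (any(dW <= 0))
    stop("disconnected kernel graph: increase knn or the kernel scale")
  S <- W / sqrt(outer(dW, dW))      # symmetric conjugate of T = D^-1 W
  eig <- eigen(S, symmetric = TRUE)
  lambda <- eig$values
  if (lambda[2] > 1 - 1e-12)
    stop("disconnected kernel graph (repeated unit eigenvalue): ",
         "increase knn or the kernel scale")
  psi <- eig$vectors / sqrt(dW)     # right eigenvectors of T
  ## fix eigenvector signs deterministically (largest-|entry| positive)
  for (k in seq_len(ncol(psi))) {
    i <- which.max(abs(psi[, k]))
    if (psi[i, k] < 0) psi[, k] <- -psi[, k]
  }
  idx <- 2:(nComponents + 1L)
  comps <- sweep(psi[, idx, drop = FALSE], 2, lambda[idx], "*")
  colnames(comps) <- paste0("DC", seq_len(nComponents))
  rownames(comps) <- colnames(x)
  Tm <- W / dW
  dimnames(Tm) <- list(colnames(x), colnames(x))
  new("DiffusionState",
      cellNames = colnames(x), eigenvalues = lambda[idx],
      components = comps, transition = Tm,
      kernelInfo = list(kernel = kernel, knn = knn,
                        stationary = dW / sum(dW)),
      root = character(0), diffusionTime = numeric(0),
      terciles = factor(character(0), levels = c("SP1", "SP2", "SP3")),
      tercileSizes = integer(0))
}

#' Choose a root cell anchored to a population label
#'
#' Looks at the two DC1-extreme deciles, picks the end with the higher
#' fraction of `anchorLabel` cells, and returns the cell with the extreme
#' DC1 coordinate at that end (lexicographically smaller id on exact
#' ties).
#'
#' @param state a [DiffusionState-class].
#' @param labels per-cell population labels, in `state` cell order.
#' @param anchorLabel the population that marks the root end (default
#'   `"P1"`).
#' @return the root cell id.
#' @export
selectRoot <- function(state, labels, anchorLabel = "P1") {
  labels <- as.character(labels)
  if (length(labels) != length(state@cellNames))
    stop("labels length must match cells")
  if (!anchorLabel %in% labels)
    stop("anchor label '", anchorLabel, "' not present")
  dc1 <- state@components[, 1]
  n <- length(dc1)
  k <- max(1L, floor(n / 10))
  ord <- order(dc1, state@cellNames)
  lowFrac <- mean(labels[ord[seq_len(k)]] == anchorLabel)
  highFrac <- mean(labels[ord[n + 1L - seq_len(k)]] == anchorLabel)
  pick <- if (lowFrac >= highFrac) ord[1] else ord[n]
  state@cellNames[pick]
}

## Ttilde with the stationary component removed; for the reversible chain
## T = D^-1 W the stationary distribution is pi = dW / sum(dW), and the
## rank-one projection removed is (1 pi^T).
.dptMatrix <- function(Tm, stationary = NULL) {
  n <- nrow(Tm)
  if (is.null(stationary)) {
    ## left Perron eigenvector of T
    e <- eigen(t(Tm))
    i <- which.min(abs(e$values - 1))
    stationary <- Re(e$vectors[, i])
    stationary <- stationary / sum(stationary)
  }
  Ttilde <- Tm - matrix(1, n, 1) %*% matrix(stationary, 1, n)
  qr.solve(diag(n) - Ttilde) - diag(n)
}

#' Diffusion time from a root cell
#'
#' @param state a [DiffusionState-class].
#' @param root root cell id (see [selectRoot()]).
#' @return named numeric vector of per-cell diffusion times;
#'   `tau[root] == 0`.
#' @export
diffusionTime <- function(state, root) {
  if (!root %in% state@cellNames) stop("unknown root cell: ", root)
  M <- tryCatch(.dptMatrix(state@transition, state@kernelInfo$stationary),
                error = function(e)
    stop("diffusion-time system (I - T~) is numerically singular: ",
         conditionMessage(e), "; check for duplicate cells or a ",
         "disconnected graph", call. = FALSE))
  r <- match(root, state@cellNames)
  tau <- sqrt(colSums((t(M) - M[r, ])^2))
  setNames(tau, state@cellNames)
}

#' Partition cells into diffusion-time terciles
#'
#' Cells are sorted by increasing diffusion time (ties broken by cell id)
#' and split into three contiguous blocks: the first `ceiling(n/3)` cells
#' form SP1 (the root-proximal tercile) and the remainder is split with
#' earlier terciles taking any extra cell, so for 469 cells the sizes are
#' 157/156/156.
#'
#' @param tau named per-cell diffusion times.
#' @return list with `assignment` (named factor SP1/SP2/SP3, in input
#'   order) and `sizes` (integer(3)).
#' @export
tercilePartition <- function(tau) {
  if (any(!is.finite(tau))) stop("diffusion times must be finite")
  n <- length(tau)
  ids <- names(tau)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  n1 <- as.integer(ceiling(n / 3))
  rem <- n - n1
  n2 <- as.integer(ceiling(rem / 2))
  n3 <- rem - n2
  ord <- order(tau, ids)
  lab <- rep(c("SP1", "SP2", "SP3"), times = c(n1, n2, n3))
  assignment <- factor(character(n), levels = c("SP1", "SP2", "SP3"))
  assignment[ord] <- lab
  names(assignment) <- ids
  list(assignment = assignment, sizes = c(SP1 = n1, SP2 = n2, SP3 = n3))
}

#' Full diffusion-state inference
#'
#' Convenience wrapper: builds the map, anchors the root, computes
#' diffusion time and the tercile partition, and returns a completed
#' [DiffusionState-class].
#'
#' @inheritParams diffusionMap
#' @param labels per-cell population labels; defaults to the matrix's
#'   `populationLabel` annotation.
#' @param anchorLabel population anchoring the SP1 end (default `"P1"`).
#' @return a [DiffusionState-class] with root, diffusion time and terciles
#'   filled in.
#' @export
computeDiffusionState <- function(x, labels = populationLabels(x),
                                  anchorLabel = "P1", nComponents = 10L,
                                  kernel = c("local_knn", "global_sigma"),
                                  knn = 30L) {
  state <- diffusionMap(x, nComponents = nComponents, kernel = kernel,
                        knn = knn)
  root <- selectRoot(state, labels, anchorLabel)
  tau <- diffusionTime(state, root)
  part <- tercilePartition(tau)
  state@root <- root
  state@diffusionTime <- tau
  state@terciles <- part$assignment
  state@tercileSizes <- as.integer(part$sizes)
  state
}
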