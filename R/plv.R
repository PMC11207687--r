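# Phase-locking value and connectivity matrices.
#
# PLV between channels x and y over N samples is the modulus of the mean
# unit phasor of the phase difference:
#
#   PLV = | (1/N) * sum_n exp(i * (phi_x[n] - phi_y[n])) |
#
# 1 means perfect phase locking, 0 none.  It depends only on phases, so it
# is invariant to any per-channel amplitude scaling of the raw signals.

#' Phase-locking value of one channel pair
#'
#' @param phase_x,phase_y Phase vectors in radians, equal length `N >= 1`.
#' @return Scalar in `[0, 1]`.
#' @examples
#' ph <- runif(1000, -pi, pi)
#' plv_pair(ph, ph)           # identical phases: exactly 1
#' plv_pair(ph, ph + 1.3)     # constant offset: still 1
#' @export
plv_pair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y) || length(phase_x) < 1L) {
    stop("phase series must have equal length N >= 1")
  }
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Full pairwise PLV matrix of a phase series
#'
#' All channel pairs at once via one complex cross-product: with `E` the
#' channels-by-samples matrix of unit phasors `exp(i*phase)`, the PLV matrix
#' is `|E E^H| / N`.
#'
#' @param phases A `phase_series` (from [instantaneous_phase()]) or a
#'   channels x samples phase matrix.
#' @param band,state,subject,segment Optional labels attached to the result.
#' @return A `plv_matrix` object: symmetric unit-diagonal matrix in `[0, 1]`
#'   with label attributes.
#' @export
plv_matrix <- function(phases, band = NA_character_, state = NA_character_,
                       subject = NA_integer_, segment = NA_integer_) {
  ph <- if (inherits(phases, "phase_series")) phases$phase else phases
  stopifnot(is.matrix(ph))
  n <- ncol(ph)
  e <- exp(1i * ph)
  m <- Mod(e %*% Conj(t(e))) / n
  m <- (m + t(m)) / 2                  # enforce exact symmetry
  diag(m) <- 1
  m <- pmin(m, 1)
  dimnames(m) <- list(rownames(ph), rownames(ph))
  structure(m, class = c("plv_matrix", "matrix"),
            band = band, state = state, subject = subject, segment = segment)
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> %dx%d  band=%s state=%s subject=%s segment=%s\n",
              nrow(x), ncol(x), attr(x, "band"), attr(x, "state"),
              attr(x, "subject"), attr(x, "segment")))
  off <- x[upper.tri(x)]
  cat(sprintf("off-diagonal: mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
  invisible(x)
}

#' Element-wise mean of PLV matrices
#'
#' Used to build the per-(band, state) average connectivity matrix across
#' subjects and segments.
#'
#' @param matrices List of equally-sized `plv_matrix` objects.
#' @param band,state Labels for the averaged matrix (default: inherited when
#'   unanimous among the inputs).
#' @return A `plv_matrix` with the group labels.
#' @export
average_matrices <- function(matrices, band = NULL, state = NULL) {
  stopifnot(length(matrices) >= 1L)
  dims <- vapply(matrices, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("matrices differ in size")
  acc <- Reduce(`+`, lapply(matrices, unclass))
  m <- acc / length(matrices)
  inherit <- function(given, field) {
    if (!is.null(given)) return(given)
    vals <- unique(vapply(matrices, function(x) as.character(attr(x, field)),
                          character(1)))
    if (length(vals) == 1L) vals else NA_character_
  }
  structure(m, class = c("plv_matrix", "matrix"),
            band = inherit(band, "band"), state = inherit(state, "state"),
            subject = NA_integer_, segment = NA_integer_)
}

#' Threshold a connectivity matrix into a network topology
#'
#' Keeps undirected edges whose PLV is at least the threshold (diagonal
#' excluded).  The 0.55 default reproduces the sparsity level used for the
#' topology maps.  `proportional = TRUE` instead keeps the strongest
#' `threshold` fraction of edges (edge-density semantics), for users who
#' read "sparsity" that way.
#'
#' @param matrix A `plv_matrix` (or plain symmetric matrix).
#' @param threshold Absolute PLV cutoff in `[0, 1]`, or the edge density kept
#'   when `proportional = TRUE`.
#' @param proportional Interpret `threshold` as an edge-density proportion.
#' @return A `network_topology` object: data frame of edges `(i, j, from,
#'   to, weight)` with `i < j`, plus the threshold as an attribute.
#' @examples
#' m <- matrix(0.6, 3, 3); diag(m) <- 1; m[1, 3] <- m[3, 1] <- 0.2
#' threshold_topology(m, 0.55)
#' @export
threshold_topology <- function(matrix, threshold = 0.55,
                               proportional = FALSE) {
  m <- unclass(matrix)
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            threshold >= 0, threshold <= 1)
  ut <- upper.tri(m)
  w <- m[ut]
  idx <- which(ut, arr.ind = TRUE)
  if (proportional) {
    k <- round(threshold * length(w))
    keep <- rank(-w, ties.method = "first") <= k
  } else {
    keep <- w >= threshold
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  edges <- data.frame(
    i = idx[keep, 1], j = idx[keep, 2],
    from = labels[idx[keep, 1]], to = labels[idx[keep, 2]],
    weight = w[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("network_topology", "data.frame"),
            threshold = threshold, n_channels = nrow(m),
            proportional = proportional)
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> %d edges over %d channels (threshold %g%s)\n",
              nrow(x), attr(x, "n_channels"), attr(x, "threshold"),
              if (attr(x, "proportional")) ", proportional" else ""))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Export a topology as edge-list CSV or GraphML
#'
#' @param topo A `network_topology`.
#' @param path Output file.
#' @param format `"csv"` or `"graphml"` (via igraph).
#' @export
write_topology <- function(topo, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(topo)[c("from", "to", "weight")], path,
                     row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      as.data.frame(topo)[c("from", "to", "weight")], directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Save / load a PLV matrix as labeled CSV
#'
#' Values as a channel-labeled CSV plus a JSON sidecar (`<path>.json`)
#' holding band, state, subject, segment and channel order.
#'
#' @param m A `plv_matrix`.
#' @param path CSV path.
#' @export
write_plv_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  meta <- list(band = attr(m, "band"), state = attr(m, "state"),
               subject = attr(m, "subject"), segment = attr(m, "segment"),
               channels = rownames(m))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_plv_matrix
#' @export
read_plv_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rownames(m) <- colnames(m) <- meta$channels
  structure(m, class = c("plv_matrix", "matrix"),
            band = meta$band, state = meta$state,
            subject = meta$subject, segment = meta$segment)
}
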