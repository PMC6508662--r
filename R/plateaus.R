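#' Segment the layers of a partition into community-structure plateaus
#'
#' Scans the layers of a multi-scale partition and groups maximal runs of
#' consecutive layers whose non-singleton community size multisets are
#' identical. In a graph with clean nested structure, the long plateaus are
#' the topological scales of the hierarchy (whole graph, large blocks,
#' medium blocks, ...), separated by short transitional runs in which
#' communities branch one at a time.
#'
#' @param p a `multiscale_partition`.
#' @param modality,slice which modality/slice to analyze.
#' @return data.frame with one row per plateau: `start_layer`, `end_layer`,
#'   `n_layers`, `n_nonsingleton`, `max_size`, and `sizes` (list column of
#'   sorted non-singleton community sizes); plus `gamma_start`/`gamma_end`
#'   when the gamma grid is known.
#' @export
scale_plateaus <- function(p, modality = 1L, slice = 1L) {
  stopifnot(inherits(p, "multiscale_partition"))
  labs <- label_matrix(p, modality = modality, slice = slice)
  l <- ncol(labs)
  sizes <- lapply(seq_len(l), function(x) {
    s <- as.integer(table(labs[, x]))
    sort(s[s >= 2L])
  })
  keys <- vapply(sizes, paste, character(1L), collapse = ",")
  runs <- rle(keys)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- data.frame(start_layer = starts, end_layer = ends,
                    n_layers = runs$lengths,
                    n_nonsingleton = vapply(sizes[starts], length, integer(1L)),
                    max_size = vapply(sizes[starts],
                                      function(s) if (length(s)) max(s) else 1L,
                                      integer(1L)))
  out$sizes <- sizes[starts]
  gg <- p$gamma_grid
  if (!is.null(gg) && length(gg) == l) {
    out$gamma_start <- gg[starts]
    out$gamma_end <- gg[ends]
  }
  out
}

#' Identify the nested scales of a consensus partition
#'
#' Reads the hierarchy off the plateau table of [scale_plateaus()]:
#' the coarse scale is the first plateau with more than one non-singleton
#' community, the next scale is the first subsequent plateau in which every
#' community of the previous scale has branched (its maximum community size
#' has dropped), and so on; a final all-singleton scale is reported when
#' some layer has no non-singleton community at all.
#'
#' @param p a `multiscale_partition` (typically a consensus partition).
#' @param min_layers minimum plateau length (in layers) for a plateau to
#'   count as a scale rather than a branching transition.
#' @param modality,slice which modality/slice to analyze.
#' @return list with `scales` (data.frame of the retained plateaus, coarse
#'   to fine), `sizes` (list of their community size multisets), and
#'   `has_singleton_scale` (logical: some layer assigns the majority of
#'   nodes to singleton communities, i.e. the hierarchy dissolves within
#'   the studied gamma range).
#' @export
consensus_scales <- function(p, min_layers = 3L, modality = 1L, slice = 1L) {
  pl <- scale_plateaus(p, modality = modality, slice = slice)
  cand <- pl[pl$n_layers >= min_layers & pl$n_nonsingleton >= 1L, , drop = FALSE]
  picked <- integer(0)
  cur_max <- Inf
  k <- which(cand$n_nonsingleton > 1L)
  start_at <- if (length(k)) k[1L] else nrow(cand) + 1L
  i <- start_at
  while (i <= nrow(cand)) {
    if (cand$max_size[i] < cur_max) {
      picked <- c(picked, i)
      cur_max <- cand$max_size[i]
    }
    i <- i + 1L
  }
  scales <- cand[picked, , drop = FALSE]
  labs <- label_matrix(p, modality = modality, slice = slice)
  n <- nrow(labs)
  frac_singleton <- vapply(seq_len(ncol(labs)), function(x) {
    s <- table(labs[, x])
    sum(s == 1L) / n
  }, numeric(1L))
  list(scales = scales,
       sizes = scales$sizes,
       has_singleton_scale = any(frac_singleton > 0.5))
}
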