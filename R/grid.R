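#' Build the 1-D spatial grid
#'
#' Two-zone grid on \[0, L\]: a fine uniform zone covering the headgroup
#' region and its immediate vicinity \[0, 2D\], where the potential and
#' permittivity vary fastest, and a coarser uniform zone on \[2D, L\]. Half
#' the intervals go to each zone, which for the default geometry (D = 0.42
#' nm, L = 12 nm) makes the fine spacing about 13 times smaller than the
#' coarse one. The fine interval count is rounded to an even number so the
#' headgroup boundary x = D falls exactly on a node, and both counts are
#' chosen so that doubling `n_nodes` nests the previous grid (dyadic
#' refinement).
#'
#' @param params an [mlpb_parameters()] object.
#' @param n_nodes total number of nodes (>= 100; default 4000).
#' @return Object of class `mlpb_grid`: list with `x` (node positions, m),
#'   `d_index` (index of the node at x = D), `n_nodes`, and the two zone
#'   spacings `h_fine`, `h_coarse` (m).
#' @export
build_grid <- function(params, n_nodes = 4000) {
  stopifnot(inherits(params, "mlpb_params"))
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 100)
    stop("n_nodes must be a single number >= 100", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  D <- params$D; L <- params$L
  if (2 * D >= L)
    stop("domain too short: need L > 2*D for the two-zone grid", call. = FALSE)
  n_int <- n_nodes - 1L
  nf <- n_int %/% 2L
  if (nf %% 2L == 1L) nf <- nf + 1L  # even count puts a node at D
  nc <- n_int - nf
  half <- nf %/% 2L
  x1 <- seq(0, D, length.out = half + 1L)
  x2 <- seq(D, 2 * D, length.out = half + 1L)
  x3 <- seq(2 * D, L, length.out = nc + 1L)
  # pin the zone boundaries exactly (seq endpoints can be off by an ulp)
  x1[c(1L, half + 1L)] <- c(0, D)
  x2[c(1L, half + 1L)] <- c(D, 2 * D)
  x3[c(1L, nc + 1L)] <- c(2 * D, L)
  x <- c(x1, x2[-1L], x3[-1L])
  structure(list(
    x = x,
    d_index = half + 1L,
    n_nodes = length(x),
    h_fine = D / half,
    h_coarse = (L - 2 * D) / nc
  ), class = "mlpb_grid")
}

#' @export
print.mlpb_grid <- function(x, ...) {
  cat(sprintf("MLPB grid: %d nodes on [0, %g nm]\n",
              x$n_nodes, max(x$x) * 1e9))
  cat(sprintf("  fine zone spacing %.4g nm, coarse %.4g nm; node %d at D\n",
              x$h_fine * 1e9, x$h_coarse * 1e9, x$d_index))
  invisible(x)
}
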