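# Places cells on a sparse sub-lattice (stride 3) of one z-layer so every
# cell has all six face neighbors free and neighborhoods never overlap;
# direction statistics can then be read off the arrival sites.
isolated_cells <- function(dom, stride = 3L) {
  d <- dom$dims
  g <- expand.grid(ix = seq(2L, d[1] - 1L, by = stride),
                   iy = seq(2L, d[2] - 1L, by = stride),
                   iz = seq(2L, d[3] - 1L, by = stride))
  sites <- callusim:::site_index(dom, g$ix, g$iy, g$iz)
  nb <- dom$nb[sites, , drop = FALSE]
  ok <- dom$cells_allowed[sites] & rowSums(nb > 0L) == 6L
  ok <- ok & rowSums(matrix(dom$cells_allowed[pmax(nb, 1L)], ncol = 6)) == 6L
  sites[ok]
}

empty_lattice <- function(dom) {
  cells <- list(occ = integer(prod(dom$dims)),
                mature = logical(prod(dom$dims)))
  class(cells) <- "cell_lattice"
  cells
}

# One-hop direction counts pooled over repeated single-step migrations of
# isolated MSCs (hop probability forced to 1 via a long step).
direction_counts <- function(dom, sites, chem, n_rep) {
  nb <- dom$nb[sites, , drop = FALSE]
  counts <- numeric(6)
  for (r in seq_len(n_rep)) {
    cells <- empty_lattice(dom)
    cells$occ[sites] <- callusim:::PHENO_MSC
    out <- migrate(cells, dom, chem, dt_hours = 60)
    for (j in 1:6) counts[j] <- counts[j] + sum(out$occ[nb[, j]] != 0L)
  }
  counts
}

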