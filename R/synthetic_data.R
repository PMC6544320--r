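#' Specify a synthetic drug-combination experiment
#'
#' Defines the ground truth for a simulated dose-response matrix: two
#' monotherapy logistic curves `(a, b, c)` (top fraction, slope, log10 IC50),
#' concentration grids including the zero-dose margins, an interaction model
#' with injectable strength `delta` (fraction units, positive = synergy),
#' Gaussian noise on the inhibition fraction, and a replicate count.
#'
#' Defaults describe a realistic cytotoxic-like screen: steep monotherapy
#' curves (slope 2) with tops 0.9 and 0.85, IC50s of 1 and 2 concentration
#' units, a 4 x 4 half-log dose grid per drug anchored so the IC50 itself is
#' a tested dose (log10 offsets -1, -0.5, 0, +0.5 around the IC50), replicate
#' noise sd 0.066 on the inhibition fraction, and 4 replicates - the
#' matrix-stage design and replicate variability reported for large published
#' combination screens.
#'
#' @param mono1,mono2 lists with `a`, `b`, `c` for the row and column drugs.
#' @param grid1,grid2 concentration vectors including 0; `NULL` uses the
#'   default half-log grid around each drug's IC50.
#' @param model interaction model generating combination cells: `"bliss"`,
#'   `"hsa"` or `"loewe"` (matching the corresponding scoring reference).
#' @param delta interaction strength added to the model expectation, fraction
#'   units.
#' @param noise_sd Gaussian noise sd on the inhibition fraction; default
#'   0.066.
#' @param n_replicates replicates per cell; default 4.
#' @param seed RNG seed making the simulation deterministic.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(mono1 = list(a = 0.90, b = 2, c = 0),
                     mono2 = list(a = 0.85, b = 2, c = log10(2)),
                     grid1 = NULL, grid2 = NULL,
                     model = c("bliss", "hsa", "loewe"),
                     delta = 0, noise_sd = 0.066, n_replicates = 4L,
                     seed = 1L) {
  model <- match.arg(model)
  default_grid <- function(mono) c(0, 10^(mono$c + c(-1, -0.5, 0, 0.5)))
  grid1 <- grid1 %||% default_grid(mono1)
  grid2 <- grid2 %||% default_grid(mono2)
  stopifnot(!is.unsorted(grid1), !is.unsorted(grid2), noise_sd >= 0,
            n_replicates >= 1)
  structure(list(mono1 = mono1, mono2 = mono2, grid1 = grid1, grid2 = grid2,
                 model = model, delta = delta, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# monotherapy expectation; dose 0 -> 0 inhibition
mono_expect <- function(mono, x) {
  ifelse(x == 0, 0, logistic3(log10(pmax(x, .Machine$double.xmin)),
                              mono$a, mono$b, mono$c))
}

# noiseless expected inhibition fraction at one cell, before clipping
cell_expect <- function(spec, x1, x2) {
  y1 <- mono_expect(spec$mono1, x1)
  y2 <- mono_expect(spec$mono2, x2)
  if (x1 == 0 && x2 == 0) return(0)
  if (x2 == 0) return(y1)
  if (x1 == 0) return(y2)
  base <- switch(spec$model,
    bliss = y1 + y2 - y1 * y2,
    hsa = max(y1, y2),
    loewe = (mono_expect(spec$mono1, x1 + x2) +
               mono_expect(spec$mono2, x1 + x2)) / 2
  )
  base + spec$delta
}

#' Simulate a full dose-response matrix
#'
#' Generates long-format response records for one block. Margin cells follow
#' the specified monotherapy curves; combination cells follow the chosen
#' reference-model expectation plus `delta`. Expectations are clipped to
#' `[0, 1]` before noise; the per-replicate Gaussian noise is not clipped, so
#' raw records can stray outside `[0, 100]` percent exactly as real screens
#' do. Deterministic for a given `seed`.
#'
#' @param spec a [sim_spec()].
#' @param block_id,cell_line identifiers stamped on the records.
#' @return a `response_records` data frame (see [read_long_table()]).
#' @export
simulate_matrix <- function(spec, block_id = "sim-1",
                            cell_line = "SIMCELL") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  cells <- expand.grid(conc_row = spec$grid1, conc_col = spec$grid2)
  mu <- clip01(mapply(function(x1, x2) cell_expect(spec, x1, x2),
                      cells$conc_row, cells$conc_col))
  out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(rep) {
    data.frame(block_id = block_id, drug_row = "drug1", drug_col = "drug2",
               conc_row = cells$conc_row, conc_col = cells$conc_col,
               inhibition = 100 * (mu + if (spec$noise_sd > 0)
                 stats::rnorm(length(mu), 0, spec$noise_sd) else 0),
               cell_line = cell_line, replicate = rep,
               stringsAsFactors = FALSE)
  }))
  attr(out, "response_kind") <- "inhibition"
  class(out) <- c("response_records", class(out))
  out
}

#' Simulate a cross-design record
#'
#' Builds the full simulated matrix and extracts the cross anchored at the
#' true IC50s (`10^c` of each monotherapy curve; with the default grids these
#' are tested doses, so the anchors are exact).
#'
#' @inheritParams simulate_matrix
#' @return a `cross_design_record` (see [extract_cross()]).
#' @export
simulate_cross <- function(spec, block_id = "sim-1", cell_line = "SIMCELL") {
  mat <- build_matrix(simulate_matrix(spec, block_id, cell_line))
  extract_cross(mat, 10^spec$mono1$c, 10^spec$mono2$c)
}
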