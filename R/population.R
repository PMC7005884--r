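#' Population growth rate from cell counts
#'
#' `GR = log(Nt / N0) / t`, the exponential growth rate implied by a change
#' in abundance over an incubation.
#'
#' @param N0 Abundance at start, cells/L (> 0).
#' @param Nt Abundance at time `t`, cells/L (> 0).
#' @param t Elapsed time, days (> 0).
#' @return Growth rate, d^-1.
#' @examples
#' growth_rate_counts(1000, 2000, 1)  # log(2)
#' @export
growth_rate_counts <- function(N0, Nt, t) {
  if (any(N0 <= 0) || any(Nt <= 0)) stop("cell counts must be positive")
  if (any(t <= 0)) stop("time must be positive")
  log(Nt / N0) / t
}

#' Doubling time from growth rate
#'
#' `DT = log(2) / GR`.
#'
#' @param gr Growth rate, d^-1 (> 0).
#' @return Doubling time, days.
#' @examples
#' doubling_time(1.2)  # 0.58 d
#' @export
doubling_time <- function(gr) {
  if (any(gr <= 0)) stop("doubling time undefined for non-positive growth rate")
  log(2) / gr
}

#' Mean abundance over an incubation
#'
#' Arithmetic mean of start and end abundances; the convention used when
#' normalizing a bulk rate by the cells that mediated it over the incubation.
#'
#' @param N0,Nt Abundances, cells/L.
#' @return Mean abundance, cells/L.
#' @export
mean_abundance <- function(N0, Nt) {
  if (any(N0 < 0) || any(Nt < 0)) stop("abundances must be non-negative")
  (N0 + Nt) / 2
}

#' Per-cell rate from a bulk rate
#'
#' Divides a bulk volumetric rate by the mean abundance of the mediating
#' population: `bulk_rate * 1e6 / abundance` converts nmol/L/d to
#' fmol/cell/d.
#'
#' @param bulk_rate Bulk rate, nmol L^-1 d^-1.
#' @param abundance Mean population abundance, cells/L (> 0).
#' @return Per-cell rate, fmol cell^-1 d^-1.
#' @examples
#' per_cell_bulk_rate(564, 1.32e7)   # 42.7 fmol/cell/d
#' @export
per_cell_bulk_rate <- function(bulk_rate, abundance) {
  if (any(abundance <= 0)) stop("abundance must be positive")
  if (any(bulk_rate < 0)) stop("bulk rate must be non-negative")
  bulk_rate * sip_constants$fmol_per_nmol / abundance
}

#' Population carbon stock
#'
#' `abundance * fgC * 1e-9` converts cells/L times fg-C/cell to µg-C/L.
#'
#' @param abundance Cells/L.
#' @param fgC Carbon quota, fg-C per cell.
#' @return Population carbon, µg-C L^-1.
#' @examples
#' population_carbon(4.15e8, 50)  # 20.75 µg-C/L
#' @export
population_carbon <- function(abundance, fgC) {
  if (any(abundance < 0) || any(fgC < 0)) stop("inputs must be non-negative")
  abundance * fgC * 1e-9
}

#' Population C-assimilation flux from per-cell rates
#'
#' `per_cell_rate * abundance * 1e-6` converts fmol-C/cell/d times cells/L
#' to nmol-C L^-1 d^-1.
#'
#' @param per_cell_c_assim Per-cell rate, fmol-C cell^-1 d^-1.
#' @param abundance Cells/L.
#' @return Population flux, nmol-C L^-1 d^-1.
#' @examples
#' population_assimilation(6.0, 1.32e7)  # 79.2 nmol-C/L/d
#' @export
population_assimilation <- function(per_cell_c_assim, abundance) {
  if (any(per_cell_c_assim < 0) || any(abundance < 0))
    stop("inputs must be non-negative")
  per_cell_c_assim * abundance / sip_constants$fmol_per_nmol
}

#' Population C-assimilation from the increase in cell counts
#'
#' An independent estimate of population C-assimilation: the new cells
#' produced over the incubation times their carbon quota.
#' `(Nt - N0) * fgC / (t * 12 * 1e6)` yields nmol-C L^-1 d^-1
#' (12 fg-C per fmol-C; 1e6 fmol per nmol).
#'
#' @param N0,Nt Abundances, cells/L.
#' @param fgC Carbon quota, fg-C per cell.
#' @param t Incubation duration, days.
#' @return Flux, nmol-C L^-1 d^-1. If `Nt < N0`, returns 0 with a warning.
#' @examples
#' c_assim_from_count_increase(1e7, 1.9e7, 100, 1)  # 75 nmol-C/L/d
#' @export
c_assim_from_count_increase <- function(N0, Nt, fgC, t) {
  if (any(t <= 0)) stop("time must be positive")
  if (any(Nt < N0)) {
    warning("cell counts decreased over the incubation; returning 0")
    return(0)
  }
  (Nt - N0) * fgC /
    (t * sip_constants$fg_per_fmol_C * sip_constants$fmol_per_nmol)
}

#' Fragments per kilobase per million read pairs
#'
#' `FPKM = mapped / (gene_length_kb * library_millions)`.
#'
#' @param mapped_read_pairs Read pairs mapped to the gene.
#' @param mean_gene_length_kb Average gene length in the reference alignment, kb.
#' @param library_read_pairs_millions Total library size, millions of read pairs.
#' @return FPKM.
#' @examples
#' marker_fpkm(300, 1.5, 20)  # 10
#' @export
marker_fpkm <- function(mapped_read_pairs, mean_gene_length_kb,
                        library_read_pairs_millions) {
  if (any(mean_gene_length_kb <= 0) || any(library_read_pairs_millions <= 0))
    stop("gene length and library size must be positive")
  if (any(mapped_read_pairs < 0)) stop("mapped read pairs must be non-negative")
  mapped_read_pairs / (mean_gene_length_kb * library_read_pairs_millions)
}

#' Gene fraction relative to a single-copy marker
#'
#' Ratio of a functional gene's FPKM to that of a universal single-copy
#' marker (e.g. rpoB or the SSU rRNA gene); values near 1 indicate that
#' essentially all cells of the population carry the gene.
#'
#' @param fpkm_gene FPKM of the gene of interest.
#' @param fpkm_single_copy_marker FPKM of the single-copy marker (> 0).
#' @return The fraction (ratio).
#' @export
gene_fraction <- function(fpkm_gene, fpkm_single_copy_marker) {
  if (any(fpkm_single_copy_marker <= 0)) stop("marker FPKM must be positive")
  fpkm_gene / fpkm_single_copy_marker
}

#' Growth rate from counts with delta-method error propagation
#'
#' Counting error on microscopy abundances is modeled as Poisson on the
#' number of cells actually counted; the delta method propagates it to the
#' growth rate: `Var(GR) = (1/c0 + 1/ct) / t^2` with `c0`, `ct` the counted
#' cells at the two timepoints.
#'
#' @param N0,Nt Abundances, cells/L.
#' @param t Days.
#' @param counted0,countedt Raw counted cells behind each abundance.
#' @return List with `gr` and `gr_se`.
#' @export
growth_rate_counts_se <- function(N0, Nt, t, counted0, countedt) {
  gr <- growth_rate_counts(N0, Nt, t)
  if (any(counted0 <= 0) || any(countedt <= 0))
    stop("counted cells must be positive")
  list(gr = gr, gr_se = sqrt(1 / counted0 + 1 / countedt) / t)
}

#' Read a cell-count table (CSV)
#'
#' Columns: `station, depth_m, taxon, timepoint` (`t0` or `t24`),
#' `cells_per_ml, filter_fields_counted` (optional `counted_cells`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station", "depth_m", "taxon", "timepoint", "cells_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  if (any(df$cells_per_ml < 0)) stop("count table ", path, ": negative counts")
  df
}
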