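#' Molarity of a dsDNA amplicon pool
#'
#' Converts a mass concentration to molar concentration using the
#' conventional average mass of a double-stranded base pair,
#' 660 g mol^-1 bp^-1: nM = ng/uL * 10^6 / (bp * 660).  Pooling by
#' molarity rather than by mass is what lets amplicon sub-pools of
#' different lengths receive their intended share of reads.
#'
#' @param concentration mass concentration in ng/uL (non-negative).
#' @param mean_length mean amplicon length in bp (positive).
#' @param bp_mass average dsDNA base-pair mass in g/mol (default 660).
#' @return Molarity in nM.
#' @examples
#' molarity(6.6, 1000)   # 10 nM
#' @export
molarity <- function(concentration, mean_length, bp_mass = 660) {
  if (any(mean_length <= 0)) stop("mean_length must be positive")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  concentration * 1e6 / (mean_length * bp_mass)
}

#' Relative read shares of pool components
#'
#' Normalises desired read counts to fractions of the run.
#'
#' @param target_reads numeric vector of desired read counts, or a data
#'   frame with a `target_reads` column.
#' @return Numeric vector of fractions summing to 1.
#' @examples
#' read_fractions(c(eDNA = 12e6, other = 13e6))   # 0.48, 0.52
#' @export
read_fractions <- function(target_reads) {
  if (is.data.frame(target_reads))
    target_reads <- setNames(target_reads$target_reads,
                             target_reads$name)
  if (any(target_reads < 0)) stop("target_reads must be >= 0")
  tot <- sum(target_reads)
  if (tot <= 0) stop("all target read counts are zero")
  target_reads / tot
}

#' Compute pooling volumes for a sequencing run
#'
#' Given each sub-pool's mean amplicon length, concentration and desired
#' read count, computes molarities and the pipetting volumes that
#' deliver reads in proportion to the targets.  The amount of library
#' (moles) each component contributes must be proportional to its
#' target reads, so volumes are proportional to
#' `target_reads / molarity`, then scaled so that either the largest
#' volume or a chosen reference component's volume equals `cap_volume`.
#'
#' The calculation is molarity-aware but clustering-efficiency-naive:
#' `efficiency` is an optional per-component multiplier on effective
#' molarity (reads obtained per mole) through which platform-specific
#' clustering biases can be modelled; it defaults to 1 for every
#' component.
#'
#' @param components data frame with columns `name`, `mean_length`
#'   (bp), `concentration` (ng/uL) and `target_reads`.
#' @param cap_volume the volume (uL) given to the scaling reference
#'   (default 10).
#' @param reference name of the component pinned at `cap_volume`;
#'   `NULL` (default) pins the largest-volume component.
#' @param min_volume warn when any positive volume falls below this
#'   pipettable minimum (default 0.5 uL).
#' @param efficiency optional numeric vector of relative clustering
#'   efficiencies (recycled), default 1.
#' @param bp_mass dsDNA base-pair mass, see [molarity()].
#' @return An object of class `pooling_plan`: the input columns plus
#'   `molarity_nM`, `fraction` (of run reads) and `volume_uL`.
#' @examples
#' comps <- data.frame(name = c("eDNA", "gDNA"),
#'                     mean_length = c(250, 500),
#'                     concentration = c(4, 20),
#'                     target_reads = c(12e6, 13e6))
#' plan_pool(comps)
#' @export
plan_pool <- function(components, cap_volume = 10, reference = NULL,
                      min_volume = 0.5, efficiency = 1,
                      bp_mass = 660) {
  need <- c("name", "mean_length", "concentration", "target_reads")
  if (!all(need %in% names(components)))
    stop("components must have columns ", paste(need, collapse = ", "))
  df <- as.data.frame(components, stringsAsFactors = FALSE)
  if (any(df$target_reads < 0)) stop("target_reads must be >= 0")
  active <- df$target_reads > 0
  if (!any(active)) stop("no component has target_reads > 0")
  dead <- active & df$concentration == 0
  if (any(dead))
    stop("component(s) with target reads but zero concentration: ",
         paste(df$name[dead], collapse = ", "))

  df$efficiency <- rep_len(efficiency, nrow(df))
  df$molarity_nM <- molarity(df$concentration, df$mean_length, bp_mass)
  df$fraction <- ifelse(active,
                        df$target_reads / sum(df$target_reads), 0)
  raw <- ifelse(active,
                df$target_reads / (df$molarity_nM * df$efficiency), 0)
  scale_to <- if (is.null(reference)) max(raw)
              else {
                i <- match(reference, df$name)
                if (is.na(i)) stop("unknown reference component: ",
                                   reference)
                if (raw[i] <= 0)
                  stop("reference component has no volume")
                raw[i]
              }
  df$volume_uL <- raw / scale_to * cap_volume
  low <- df$volume_uL > 0 & df$volume_uL < min_volume
  if (any(low))
    warning("volume(s) below the pipettable minimum of ", min_volume,
            " uL: ", paste(df$name[low], collapse = ", "),
            " -- consider diluting or raising cap_volume")
  structure(df, cap_volume = cap_volume, min_volume = min_volume,
            class = c("pooling_plan", "data.frame"))
}

#' @export
print.pooling_plan <- function(x, ...) {
  cat(sprintf("Pooling plan for %d components (reference volume %g uL)\n",
              nrow(x), attr(x, "cap_volume")))
  df <- as.data.frame(x)
  df$molarity_nM <- round(df$molarity_nM, 2)
  df$fraction <- round(df$fraction, 4)
  df$volume_uL <- round(df$volume_uL, 1)
  print(df[, c("name", "mean_length", "concentration", "target_reads",
               "molarity_nM", "fraction", "volume_uL")], ...)
  invisible(x)
}

#' Read pool components / write a pooling plan as CSV
#'
#' @param path file path; components CSV needs columns `name`,
#'   `mean_length`, `concentration`, `target_reads`.
#' @return `read_pool_components()` returns a data frame ready for
#'   [plan_pool()]; `write_pooling_plan()` writes the plan (volumes
#'   rounded to 0.1 uL) and returns `path` invisibly.
#' @export
read_pool_components <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @param plan a [plan_pool()] result.
#' @rdname read_pool_components
#' @export
write_pooling_plan <- function(plan, path) {
  df <- as.data.frame(plan)
  df$molarity_nM <- round(df$molarity_nM, 3)
  df$fraction <- round(df$fraction, 4)
  df$volume_uL <- round(df$volume_uL, 1)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
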