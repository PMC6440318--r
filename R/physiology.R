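#' Relative water content of a leaf sample
#'
#' RWC = 100 * (FW - DW) / (TW - DW), where FW is the fresh weight at
#' sampling, TW the turgid weight after re-hydration and DW the oven-dry
#' weight (all grams). A fully turgid leaf scores 100, a fully dry one
#' 0. Values outside [0, 100] arise from weighing error or sample
#' degradation (DW <= FW <= TW violated); they are returned unchanged
#' and flagged, never clamped.
#'
#' @param fw,tw,dw fresh, turgid and dry weights, g (vectorized).
#' @return numeric vector of RWC percentages with a logical attribute
#'   \code{out_of_range} marking physically invalid samples.
#' @export
#' @examples
#' compute_rwc(5, 6, 1) # 80
compute_rwc <- function(fw, tw, dw) {
  n <- max(length(fw), length(tw), length(dw))
  fw <- rep_len(fw, n); tw <- rep_len(tw, n); dw <- rep_len(dw, n)
  if (any(tw <= dw)) {
    stop("degenerate-sample error: turgid weight must exceed dry weight",
         call. = FALSE)
  }
  rwc <- 100 * (fw - dw) / (tw - dw)
  flag <- rwc < 0 | rwc > 100
  if (any(flag)) {
    warning(sum(flag), " sample(s) outside [0, 100] %RWC (weights violate ",
            "DW <= FW <= TW); flagged, not clamped", call. = FALSE)
  }
  structure(rwc, out_of_range = flag)
}

#' RWC table with per-plant aggregation
#'
#' Appends an \code{rwc_pct} column to a sample table (columns
#' \code{plant_id, sample_id, fw_g, tw_g, dw_g}) and summarizes per
#' plant as the mean over its leaf samples (protocols take at least two
#' mature leaves per plant; plants with fewer are flagged).
#'
#' @param samples data frame of leaf samples.
#' @return list with \code{samples} (input plus \code{rwc_pct} and
#'   \code{out_of_range}) and \code{plants} (per-plant \code{n_samples},
#'   \code{rwc_mean}, \code{underreplicated}).
#' @export
rwc_table <- function(samples) {
  req <- c("plant_id", "sample_id", "fw_g", "tw_g", "dw_g")
  missing <- setdiff(req, names(samples))
  if (length(missing)) {
    stop("format error: RWC table lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rwc <- compute_rwc(samples$fw_g, samples$tw_g, samples$dw_g)
  samples$rwc_pct <- as.numeric(rwc)
  samples$out_of_range <- attr(rwc, "out_of_range")
  agg <- stats::aggregate(rwc_pct ~ plant_id, data = samples, FUN = mean)
  cnt <- stats::aggregate(sample_id ~ plant_id, data = samples,
                          FUN = length)
  plants <- merge(cnt, agg, by = "plant_id")
  names(plants) <- c("plant_id", "n_samples", "rwc_mean")
  plants$underreplicated <- plants$n_samples < 2
  list(samples = samples, plants = plants[order(plants$plant_id), ])
}
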