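#' Summarize tri-phase parameters by group
#'
#' Per-group means and standard deviations of the thermal rate (um
#' degC^-1 h^-1) and the two breakpoints (log10 hPa), for comparing
#' replicated experiments or genotypes. The standard deviation is absent
#' (\code{NA}) for singleton groups.
#'
#' @param results flat per-tiller result table (see [as_result_row()]).
#' @param grouping data frame with \code{tiller_id} and \code{group_id};
#'   every tiller in \code{results} must be mapped.
#' @return data frame ordered by \code{group_id} with \code{n} and
#'   mean/sd columns for \code{a_um}, \code{sigma_upper},
#'   \code{sigma_lower}.
#' @export
summarize_groups <- function(results, grouping) {
  stopifnot(all(c("tiller_id", "group_id") %in% names(grouping)))
  unknown <- setdiff(results$tiller_id, grouping$tiller_id)
  if (length(unknown)) {
    stop("mapping error: no group for tiller(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- merge(results, grouping[, c("tiller_id", "group_id")],
             by = "tiller_id")
  params <- c("a_um", "sigma_upper", "sigma_lower")
  groups <- sort(unique(m$group_id))
  rows <- lapply(groups, function(g) {
    d <- m[m$group_id == g, , drop = FALSE]
    row <- data.frame(group_id = g, n = nrow(d), stringsAsFactors = FALSE)
    for (p in params) {
      row[[paste0(p, "_mean")]] <- mean(d[[p]])
      row[[paste0(p, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[p]]) else
        NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Classical one-way ANOVA for a tri-phase parameter
#'
#' Standard fixed-effects one-way F test (between-group mean square over
#' within-group mean square), as \code{aov} would compute it, with one
#' degenerate case handled explicitly: if every value is identical, F is
#' 0 and p is 1.
#'
#' @param values numeric vector of per-tiller parameter estimates.
#' @param groups group labels, same length as \code{values}.
#' @param parameter optional name carried into the result.
#' @return list of class \code{anova_result} with \code{parameter},
#'   \code{f_stat}, \code{df_between}, \code{df_within}, \code{p_value}.
#' @export
one_way_anova <- function(values, groups, parameter = NA_character_) {
  ok <- is.finite(values)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  k <- length(unique(groups))
  n <- length(values)
  if (k < 2) {
    stop("anova error: need >= 2 groups", call. = FALSE)
  }
  if (n - k < 1) {
    stop("anova error: no within-group degrees of freedom", call. = FALSE)
  }
  grand <- mean(values)
  group_means <- tapply(values, groups, mean)
  group_n <- tapply(values, groups, length)
  ssb <- sum(group_n * (group_means - grand)^2)
  ssw <- sum((values - group_means[groups])^2)
  df_b <- k - 1
  df_w <- n - k
  if (ssw == 0 && ssb == 0) {
    f <- 0
    p <- 1
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(parameter = parameter, f_stat = f, df_between = df_b,
                 df_within = df_w, p_value = p),
            class = "anova_result")
}

#' One-way ANOVA across groups for all three tri-phase parameters
#'
#' Runs [one_way_anova()] for the thermal rate and both breakpoints.
#' P-values are reported raw, one per parameter, without multiplicity
#' correction.
#'
#' @inheritParams summarize_groups
#' @return data frame with one row per parameter: \code{parameter},
#'   \code{f_stat}, \code{df_between}, \code{df_within}, \code{p_value}.
#' @export
anova_table <- function(results, grouping) {
  m <- merge(results, grouping[, c("tiller_id", "group_id")],
             by = "tiller_id")
  params <- c("a_um", "sigma_upper", "sigma_lower")
  rows <- lapply(params, function(p) {
    res <- one_way_anova(m[[p]], m$group_id, parameter = p)
    as.data.frame(unclass(res), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
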