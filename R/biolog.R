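## Community-level physiological profiling from EcoPlate readings: blank
## correction, AWCD, substrate/guild profiles and the three functional
## diversity indices (Shannon-Wiener H', Simpson D, McIntosh U).

#' Blank-correct plate signals at one read time
#'
#' Subtracts each plate's blank (Water) well signal from every substrate
#' well at the chosen read time and clips at zero, the dominant convention
#' in EcoPlate work (it also guarantees nonnegative well proportions for
#' the diversity indices). If a plate lacks a blank well the blank is
#' taken as zero with a warning.
#'
#' @param plates a \code{plate_readings} object.
#' @param time_h read time in hours (default 96, the plateau read point).
#' @return a \code{substrate_profile}: list with \code{activity} (samples
#'   x 31 matrix of blank-corrected signals), \code{time_h}, and the
#'   substrate \code{guild} map.
#' @export
blank_correct <- function(plates, time_h = 96) {
  stopifnot(inherits(plates, "plate_readings"))
  at <- plates[plates$time_h == time_h, , drop = FALSE]
  if (nrow(at) == 0L)
    stop2("time ", time_h, " h is not on the plate time grid")
  samples <- unique(plates$sample_id)
  subs <- eco_substrates()$substrate
  act <- matrix(NA_real_, length(samples), length(subs),
                dimnames = list(samples, subs))
  for (s in samples) {
    r <- at[at$sample_id == s, ]
    bl <- r$signal[r$substrate == "Water"]
    if (length(bl) == 0L) {
      warn2("sample ", s, " has no blank well; using blank = 0")
      bl <- 0
    }
    blank <- mean(bl)
    v <- r$signal[match(subs, r$substrate)]
    act[s, ] <- pmax(v - blank, 0)
  }
  structure(list(activity = act, time_h = time_h,
                 guild = stats::setNames(eco_substrates()$guild, subs)),
            class = "substrate_profile")
}

#' @export
print.substrate_profile <- function(x, ...) {
  cat("<substrate_profile> ", nrow(x$activity), " samples x ",
      ncol(x$activity), " substrates at ", x$time_h, " h\n", sep = "")
  invisible(x)
}

#' Average well color development
#'
#' \eqn{AWCD = \frac{1}{31}\sum_{i=1}^{31} c_i} over the blank-corrected
#' substrate activities \eqn{c_i}; the standard summary of overall
#' carbon-source metabolic activity on an EcoPlate.
#'
#' @param profile a \code{substrate_profile} from [blank_correct()].
#' @return named numeric vector, one AWCD value per sample.
#' @export
awcd <- function(profile) {
  stopifnot(inherits(profile, "substrate_profile"))
  rowMeans(profile$activity)
}

#' Functional diversity indices of a substrate profile
#'
#' With well proportions \eqn{p_i = c_i / \sum c}: Shannon-Wiener
#' \eqn{H' = -\sum p_i \ln p_i} (natural log, over \eqn{p_i > 0}), Simpson
#' \eqn{D = 1 - \sum p_i^2} (option \code{simpson = "inverse"} reports
#' \eqn{1/\sum p_i^2} instead), and McIntosh \eqn{U = \sqrt{\sum c_i^2}}
#' (the unnormalized index). Samples with all-zero activity get \code{NA}
#' for H' and D (undefined) and \eqn{U = 0}, with a warning.
#'
#' @param profile a \code{substrate_profile}.
#' @param simpson \code{"complement"} (default, \eqn{1-\sum p^2}) or
#'   \code{"inverse"}.
#' @return data frame with columns \code{sample_id}, \code{H_prime},
#'   \code{D_simpson}, \code{U_mcintosh}.
#' @export
functional_diversity <- function(profile, simpson = c("complement", "inverse")) {
  stopifnot(inherits(profile, "substrate_profile"))
  simpson <- match.arg(simpson)
  a <- profile$activity
  tot <- rowSums(a)
  H <- D <- rep(NA_real_, nrow(a))
  ok <- tot > 0
  if (any(!ok)) warn2("all-zero activity for sample(s): ",
                      paste(rownames(a)[!ok], collapse = ", "))
  if (any(ok)) {
    p <- a[ok, , drop = FALSE] / tot[ok]
    H[ok] <- apply(p, 1L, function(q) -sum(q[q > 0] * log(q[q > 0])))
    sp2 <- rowSums(p^2)
    D[ok] <- if (simpson == "complement") 1 - sp2 else 1 / sp2
  }
  data.frame(sample_id = rownames(a), H_prime = H, D_simpson = D,
             U_mcintosh = sqrt(rowSums(a^2)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' AWCD over incubation time
#'
#' Blank-corrects every read time independently and reports the AWCD
#' curve, one value per (sample, time). Under logistic color development
#' the curve is nondecreasing and plateaus (by design around 96 h).
#'
#' @param plates a \code{plate_readings} object.
#' @return data frame with columns \code{sample_id}, \code{time_h},
#'   \code{awcd}.
#' @export
awcd_timeseries <- function(plates) {
  stopifnot(inherits(plates, "plate_readings"))
  times <- sort(unique(plates$time_h))
  out <- lapply(times, function(t) {
    v <- awcd(suppressWarnings(blank_correct(plates, time_h = t)))
    data.frame(sample_id = names(v), time_h = t, awcd = unname(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean activity per substrate guild
#'
#' Averages blank-corrected activity within each of the six conventional
#' EcoPlate substrate guilds (carbohydrates, carboxylic acids, amino
#' acids, polymers, amines, phenolic compounds).
#'
#' @param profile a \code{substrate_profile}.
#' @return samples x 6 matrix of guild means.
#' @export
guild_activity <- function(profile) {
  stopifnot(inherits(profile, "substrate_profile"))
  g <- profile$guild[colnames(profile$activity)]
  if (any(is.na(g)))
    stop2("substrate(s) without a guild mapping", class = "config_error")
  t(rowsum(t(profile$activity), group = g) / as.vector(table(g)[sort(unique(g))]))
}
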