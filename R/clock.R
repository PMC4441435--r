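# Wireless clock synchronisation from beacon transmitters.

#' Estimate and remove per-hydrophone clock offset and drift
#'
#' Wireless hydrophones log on their own clocks; known-position beacon
#' transmitters on a known emission schedule let each hydrophone's clock
#' error be modelled as `offset + drift * t` and subtracted. For each
#' wireless hydrophone the clock error of every beacon detection is the
#' observed TOA minus the true TOA (emission time plus slant range over the
#' speed of sound); a linear fit of these errors on time gives the
#' correction. Residual synchronisation error persists and is the wireless
#' system's accuracy penalty.
#'
#' @param log Detection tibble whose `toa_s` should be corrected.
#' @param beacon_log Tibble from beacon reception: `hydrophone_id`,
#'   `t_emit`, `x`, `y`, `depth` (beacon position), `toa_s`.
#' @param hydrophones Hydrophone tibble (`hydrophone_id`, `x`, `y`, `depth`,
#'   `mode`).
#' @param c_sound Speed of sound (m/s).
#' @return List: `log` (corrected detections), `clock_fits` (per-hydrophone
#'   `offset`, `drift`, `n_beacon`), `flagged` (hydrophone ids with fewer
#'   than 2 beacon detections, left uncorrected). Wired logs are returned
#'   unchanged.
#' @export
apply_clock_model <- function(log, beacon_log, hydrophones, c_sound) {
  wireless_ids <- hydrophones$hydrophone_id[hydrophones$mode == "wireless"]
  if (length(wireless_ids) == 0) {
    return(list(log = log, clock_fits = tibble(), flagged = character()))
  }
  fits <- list()
  flagged <- character()
  log_out <- log
  for (hid in wireless_ids) {
    h <- hydrophones[hydrophones$hydrophone_id == hid, ]
    b <- beacon_log %>% filter(.data$hydrophone_id == hid)
    if (nrow(b) < 2) {
      flagged <- c(flagged, hid)
      next
    }
    r3 <- sqrt((b$x - h$x)^2 + (b$y - h$y)^2 + (b$depth - h$depth)^2)
    true_toa <- b$t_emit + r3 / c_sound
    # forward model: toa_obs = offset + (1 + drift) * toa_true; fit the
    # affine map and invert it exactly
    fit <- lm(b$toa_s ~ true_toa)
    a <- unname(coef(fit)[1]); slope <- unname(coef(fit)[2])
    sel <- log_out$hydrophone_id == hid
    log_out$toa_s[sel] <- (log_out$toa_s[sel] - a) / slope
    fits[[hid]] <- tibble(hydrophone_id = hid, offset = a,
                          drift = slope - 1, n_beacon = nrow(b))
  }
  list(log = log_out, clock_fits = bind_rows(fits), flagged = flagged)
}
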