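# Synthetic lake fixtures: perimeter, bathymetry, habitat map.
#
# Two shipped fixtures emulate the shape of typical whole-lake APT test sites:
# "lake1" — a 25 ha lake with a 20-hydrophone wireless array, all six habitat
# categories; "lake2" — a 1 ha pond with an 8-hydrophone cabled array and no
# submerged-macrophyte habitats. Both are elliptical basins with a parabolic
# bowl bathymetry; habitats are concentric vegetation rings (dense then loose
# emergent macrophytes near shore), open water split by depth, and (lake1
# only) two submerged-macrophyte patches.

HABITAT_LEVELS <- c("SD", "SA", "OS", "OD", "EL", "ED")

#' Construct a synthetic lake fixture
#'
#' @param name `"lake1"` (25 ha, 7.6 m deep, 17.1 degC, all six habitats) or
#'   `"lake2"` (1 ha, 8 m deep, 5.4 degC, no submerged macrophytes).
#' @return An object of class `apt_lake`: perimeter polygon (local ENU metres,
#'   origin at the lake centroid), bathymetry and habitat-map parameters, and
#'   the mixed-column water temperature.
#' @export
apt_lake <- function(name = c("lake1", "lake2")) {
  name <- match.arg(name)
  if (name == "lake1") {
    lake <- list(
      name = "lake1", a = 320, b = 250, max_depth = 7.6,
      temperature_c = 17.1, deep_threshold = 4.5,
      ring_ed = 0.92, ring_el = 0.82,
      patches = tibble(
        habitat = c("SD", "SA"),
        x = c(-100, 120), y = c(60, -70), radius = c(50, 50)
      ),
      habitats = HABITAT_LEVELS
    )
  } else {
    lake <- list(
      name = "lake2", a = 64, b = 50, max_depth = 8,
      temperature_c = 5.4, deep_threshold = 4.5,
      ring_ed = 0.92, ring_el = 0.82,
      patches = tibble(habitat = character(), x = numeric(),
                       y = numeric(), radius = numeric()),
      habitats = c("OS", "OD", "EL", "ED")
    )
  }
  theta <- seq(0, 2 * pi, length.out = 97)[-97]
  lake$perimeter <- tibble(x = lake$a * cos(theta), y = lake$b * sin(theta))
  class(lake) <- "apt_lake"
  lake
}

#' @export
print.apt_lake <- function(x, ...) {
  cat(sprintf("<apt_lake '%s'>  area %.1f ha, max depth %.1f m, %.1f degC\n",
              x$name, polygon_area(x$perimeter) / 1e4, x$max_depth,
              x$temperature_c))
  cat("habitats:", paste(x$habitats, collapse = " "), "\n")
  invisible(x)
}

# Normalised elliptical radius (0 at centre, 1 at shoreline).
lake_rho <- function(lake, x, y) sqrt((x / lake$a)^2 + (y / lake$b)^2)

#' Water depth at locations inside a lake
#'
#' Parabolic bowl: `max_depth * (1 - rho^2)` where `rho` is the normalised
#' elliptical radius; zero outside the perimeter.
#'
#' @param lake An [apt_lake()] fixture.
#' @param x,y Coordinates (m ENU).
#' @return Depth in m (positive down).
#' @export
lake_depth <- function(lake, x, y) {
  pmax(0, lake$max_depth * (1 - lake_rho(lake, x, y)^2))
}

#' Habitat category at locations inside a lake
#'
#' @inheritParams lake_depth
#' @return Character vector of habitat codes: `SD` (dense submerged
#'   macrophytes), `SA` (above submerged macrophytes), `OS` (shallow open
#'   water), `OD` (deep open water), `EL` (loose emergent macrophytes), `ED`
#'   (dense emergent macrophytes); `NA` outside the perimeter.
#' @export
lake_habitat <- function(lake, x, y) {
  rho <- lake_rho(lake, x, y)
  out <- rep(NA_character_, length(x))
  inside <- rho <= 1
  out[inside & rho > lake$ring_ed] <- "ED"
  out[inside & rho > lake$ring_el & rho <= lake$ring_ed] <- "EL"
  open <- inside & rho <= lake$ring_el
  deep <- lake_depth(lake, x, y) >= lake$deep_threshold
  out[open & deep] <- "OD"
  out[open & !deep] <- "OS"
  if (nrow(lake$patches) > 0) {
    for (i in seq_len(nrow(lake$patches))) {
      p <- lake$patches[i, ]
      hit <- open & sqrt((x - p$x)^2 + (y - p$y)^2) <= p$radius
      out[hit] <- p$habitat
    }
  }
  out
}

# Rejection-sample n sites of a given habitat (uses the current RNG stream).
sample_habitat_sites <- function(lake, habitat, n) {
  out <- matrix(numeric(0), ncol = 2)
  guard <- 0
  while (nrow(out) < n) {
    m <- max(50, 20 * n)
    x <- runif(m, -lake$a, lake$a)
    y <- runif(m, -lake$b, lake$b)
    keep <- !is.na(lake_habitat(lake, x, y)) &
      lake_habitat(lake, x, y) == habitat
    out <- rbind(out, cbind(x[keep], y[keep]))
    guard <- guard + 1
    if (guard > 200) stop("habitat '", habitat, "' not found in lake '",
                          lake$name, "'", call. = FALSE)
  }
  tibble(x = out[seq_len(n), 1], y = out[seq_len(n), 2])
}

# Hydrophone layout for each fixture; geometry is deterministic, wireless
# clock parameters are drawn by the scenario builder.
lake_hydrophone_layout <- function(lake) {
  if (lake$name == "lake1") {
    th_outer <- seq(0, 2 * pi, length.out = 13)[-13]
    th_inner <- seq(0, 2 * pi, length.out = 8)[-8] + pi / 7
    tibble(
      hydrophone_id = sprintf("H%02d", 1:20),
      x = c(0.82 * lake$a * cos(th_outer), 0.45 * lake$a * cos(th_inner), 0),
      y = c(0.82 * lake$b * sin(th_outer), 0.45 * lake$b * sin(th_inner), 0),
      depth = 2,
      mode = "wireless"
    )
  } else {
    th <- seq(0, 2 * pi, length.out = 9)[-9] + pi / 8
    tibble(
      hydrophone_id = sprintf("H%02d", 1:8),
      x = 0.80 * lake$a * cos(th),
      y = 0.80 * lake$b * sin(th),
      depth = 1,
      mode = "wired"
    )
  }
}
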