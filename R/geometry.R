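#' Wrap coordinates onto the torus
#'
#' Maps positions into `[0, width) x [0, height)`; the world wraps around
#' horizontally and vertically.
#'
#' @param x,y numeric coordinates (vectorized).
#' @param width,height world extent in patches.
#' @return A list with wrapped `x` and `y`.
#' @examples
#' wrap_position(161.5, 80, 161, 161)  # x -> 0.5
#' @export
wrap_position <- function(x, y, width = 161, height = 161) {
  list(x = ((x %% width) + width) %% width,
       y = ((y %% height) + height) %% height)
}

#' Toroidal (minimum-image) distance
#'
#' @param x1,y1,x2,y2 coordinates (vectorized).
#' @param width,height world extent in patches.
#' @return Euclidean distance under the minimum-image convention.
#' @examples
#' torus_distance(0, 0, 160, 0, width = 161)  # 1, not 160
#' @export
torus_distance <- function(x1, y1, x2, y2, width = 161, height = 161) {
  dx <- abs(x1 - x2); dx <- pmin(dx, width - dx)
  dy <- abs(y1 - y2); dy <- pmin(dy, height - dy)
  sqrt(dx^2 + dy^2)
}

#' Is an agent class due to move at a given tick?
#'
#' Molecular agents (LPS, cytokines, intracellular signaling molecules) move
#' every tick; cellular agents (macrophages, T-helper cells) move once per
#' `cell_move_interval` ticks, so molecules move `cell_move_interval` (800 by
#' default) times more frequently than cells.
#'
#' @param agent_class `"molecular"` or `"cellular"` (aliases: specific agent
#'   names such as `"LPS"`, `"macrophage"`, `"Th0"` are accepted).
#' @param tick non-negative tick index (vectorized).
#' @param params parameter set, see [default_params()].
#' @return logical vector.
#' @export
movement_due <- function(agent_class, tick, params = default_params()) {
  cellular <- c("cellular", "macrophage", "th", "th0", "th1", "th2")
  molecular <- c("molecular", "lps", "tnf", "il12", "il4", "ikk", "nfkb",
                 "ikba", "inhibitor")
  cls <- tolower(agent_class)
  if (cls %in% cellular) return(tick %% params$cell_move_interval == 0)
  if (cls %in% molecular) return(rep(TRUE, length(tick)))
  stop("unknown agent class: ", agent_class, call. = FALSE)
}

#' One unbiased random-walk move
#'
#' Draws a uniform heading on [0, 360) degrees and advances `step_len` patch
#' units along it (the published movement routine for free molecules).  Uses
#' R's RNG stream; the compiled engine uses its own stream with the same rule.
#'
#' @param x,y current position.
#' @param step_len move length in patches.
#' @param width,height world extent.
#' @return list with new `x`, `y` and the drawn `heading` (degrees).
#' @export
random_walk <- function(x, y, step_len, width = 161, height = 161) {
  a <- runif(length(x)) * 2 * pi
  p <- wrap_position(x + step_len * cos(a), y + step_len * sin(a),
                     width, height)
  list(x = p$x, y = p$y, heading = a * 180 / pi)
}

# 8-sector index of an offset: 0 = +x, counter-clockwise, 45 degrees each.
sector_index <- function(dx, dy) {
  a <- atan2(dy, dx)
  (floor((a + pi / 8) / (pi / 4)) %% 8 + 8) %% 8
}

#' Chemotactic heading of a macrophage
#'
#' The cell senses free LPS within `5 + cell_radius` patches and turns toward
#' the 45-degree sector with the highest count (ties broken by the lowest
#' sector index, sector 0 pointing east); with no LPS in range the heading is
#' unchanged.  Headings are reported compass-style (0 = north, 90 = east).
#'
#' @param center length-2 numeric, cell center.
#' @param lps matrix or data.frame with columns `x`, `y` of free LPS positions.
#' @param heading current compass heading in degrees.
#' @param params parameter set.
#' @return new compass heading in degrees.
#' @export
macrophage_chemotaxis <- function(center, lps, heading = 0,
                                  params = default_params()) {
  if (is.null(dim(lps)) || nrow(lps) == 0) return(heading)
  w <- params$width; h <- params$height
  dx <- (lps[, 1] - center[1] + w / 2) %% w - w / 2
  dy <- (lps[, 2] - center[2] + h / 2) %% h - h / 2
  r <- 5 + params$cell_radius
  keep <- dx^2 + dy^2 <= r^2
  if (!any(keep)) return(heading)
  counts <- tabulate(sector_index(dx[keep], dy[keep]) + 1, nbins = 8)
  best <- which.max(counts) - 1          # which.max takes the first maximum
  math_deg <- best * 45
  (90 - math_deg) %% 360
}
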