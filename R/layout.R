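#' Insole sensor layout
#'
#' An insole carries eight piezoresistive sensors per foot, one per anatomical
#' loading site. The canonical map used throughout the package is:
#' 1 = hallux, 2 = 1st metatarsal head, 3 = 3rd metatarsal head,
#' 4 = 5th metatarsal head, 5 = medial midfoot, 6 = lateral midfoot,
#' 7 = medial heel, 8 = lateral heel. Coordinates are normalised foot units:
#' x is mediolateral in [-1, 1] (negative = medial for the left foot; the
#' right foot is the mediolateral mirror image), y is anteroposterior in
#' [0, 1] with 0 at the heel. Only relative geometry matters for the
#' centre-of-pressure features, so the defaults are configurable via
#' \code{read_layout()}.
#'
#' @param coords optional 8x2 matrix of (x, y) coordinates for the left foot,
#'   rows in sensor index order; the right foot is derived by mirroring x.
#' @return An object of class \code{sensor_layout}: a data frame with one row
#'   per sensor and foot (16 rows), columns \code{foot}, \code{index},
#'   \code{region}, \code{x}, \code{y}, plus attributes \code{forefoot_set}
#'   and \code{rearfoot_set} (sensor indices).
#' @examples
#' lay <- default_layout()
#' subset(lay, foot == "R" & index == 8)  # lateral heel, right foot
#' @export
default_layout <- function(coords = NULL) {
  regions <- c("hallux", "metatarsal", "metatarsal", "metatarsal",
               "midfoot", "midfoot", "heel", "heel")
  if (is.null(coords)) {
    coords <- matrix(c(
      -0.20, 0.95,   # hallux
      -0.35, 0.75,   # 1st metatarsal head
       0.00, 0.75,   # 3rd metatarsal head
       0.35, 0.72,   # 5th metatarsal head
      -0.25, 0.45,   # medial midfoot
       0.30, 0.45,   # lateral midfoot
      -0.20, 0.10,   # medial heel
       0.20, 0.10    # lateral heel
    ), ncol = 2, byrow = TRUE)
  }
  stopifnot(is.matrix(coords), nrow(coords) == 8, ncol(coords) == 2)
  lay <- data.frame(
    foot   = rep(c("L", "R"), each = 8),
    index  = rep(1:8, 2),
    region = rep(regions, 2),
    x      = c(coords[, 1], -coords[, 1]),  # mediolateral mirror
    y      = rep(coords[, 2], 2),
    stringsAsFactors = FALSE
  )
  structure(lay,
            class = c("sensor_layout", "data.frame"),
            forefoot_set = 1:4,
            rearfoot_set = 7:8)
}

validate_layout <- function(layout) {
  stopifnot(inherits(layout, "sensor_layout"))
  for (f in c("L", "R")) {
    if (!identical(sort(layout$index[layout$foot == f]), 1:8))
      stop_plantar("layout must have exactly sensors 1..8 per foot",
                   "layout_error")
  }
  ff <- attr(layout, "forefoot_set")
  rf <- attr(layout, "rearfoot_set")
  if (length(intersect(ff, rf)) > 0)
    stop_plantar("forefoot and rearfoot sets must be disjoint", "layout_error")
  l <- layout[layout$foot == "L", ][order(layout$index[layout$foot == "L"]), ]
  r <- layout[layout$foot == "R", ][order(layout$index[layout$foot == "R"]), ]
  if (max(abs(l$x + r$x)) > 1e-9 || max(abs(l$y - r$y)) > 1e-9)
    stop_plantar("left/right coordinates must mirror in x and match in y",
                 "layout_error")
  invisible(layout)
}

#' Read or write a sensor layout as JSON
#'
#' The JSON format is a list of \code{{foot, index, region, x, y}} records;
#' forefoot/rearfoot membership is carried in a top-level object.
#'
#' @param path file path.
#' @param layout a \code{sensor_layout}.
#' @return \code{read_layout}: a validated \code{sensor_layout};
#'   \code{write_layout}: \code{path}, invisibly.
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- as.data.frame(obj$sensors, stringsAsFactors = FALSE)
  lay <- structure(lay,
                   class = c("sensor_layout", "data.frame"),
                   forefoot_set = as.integer(obj$forefoot_set),
                   rearfoot_set = as.integer(obj$rearfoot_set))
  validate_layout(lay)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  obj <- list(sensors = as.data.frame(layout),
              forefoot_set = attr(layout, "forefoot_set"),
              rearfoot_set = attr(layout, "rearfoot_set"))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
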