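#' Persistence diagrams of a superlevel filtration
#'
#' Tracks the connected components (dimension 0) and holes (dimension 1) of
#' the superlevel sets of a [filtration_field()] as the threshold decreases
#' from the maximum to the minimum value. Components are merged under the
#' elder rule with 8-connectivity; holes are found by Alexander duality as the
#' bounded 4-connected components of the complement. Each pair records the
#' filtration values and the grid positions where the feature appears
#' (`birth_row`, `birth_col`) and where it is merged or filled in
#' (`death_row`, `death_col`). The single component that survives to the end
#' is `essential`, with the field minimum as its death sentinel.
#' Zero-persistence pairs (birth equal to death) are dropped.
#'
#' @param field a [filtration_field()], or a bare numeric matrix (treated as a
#'   field with spacing 1).
#' @param ... unused.
#' @return a `persistence_diagram`: a tibble with columns `dim`, `birth`,
#'   `death`, `birth_row`, `birth_col`, `death_row`, `death_col`, `essential`,
#'   carrying the source filtration, grid spacing/origin and log-scale state
#'   as attributes.
#' @examples
#' f <- matrix(200, 3, 3); f[2, 2] <- 0     # a bright ring around a dark pit
#' compute_persistence(f)                   # one component, one hole (200, 0)
#' @export
compute_persistence <- function(field, ...) {
  UseMethod("compute_persistence")
}

#' @export
compute_persistence.matrix <- function(field, ...) {
  compute_persistence(filtration_field(field + 0), ...)
}

#' @export
compute_persistence.filtration_field <- function(field, ...) {
  df <- cpp_superlevel_persistence(field$values)
  new_persistence_diagram(tibble::as_tibble(df),
                          source = field$filtration,
                          spacing = field$spacing,
                          origin = field$origin,
                          log_scaled = FALSE)
}

new_persistence_diagram <- function(data, source = "custom", spacing = 1,
                                    origin = c(1, 1), log_scaled = FALSE) {
  structure(data,
            class = c("persistence_diagram", class(tibble::tibble())),
            source = source, spacing = spacing, origin = origin,
            log_scaled = log_scaled)
}

#' @exportS3Method base::print
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram: %s%s> %d pairs (%d components, %d holes)\n",
              attr(x, "source"), if (attr(x, "log_scaled")) ", log-scaled" else "",
              nrow(x), sum(x$dim == 0), sum(x$dim == 1)))
  NextMethod()
}

#' Log-scale a persistence diagram
#'
#' Replaces births and deaths by their natural logarithm, the convention used
#' for the kNN density filtration where values span orders of magnitude.
#' Refuses diagrams containing non-positive values (signed-distance and
#' grayscale diagrams stay on the raw scale).
#'
#' @param diagram a [compute_persistence()] result.
#' @return the diagram with transformed values and `log_scaled = TRUE`.
#' @export
log_scale_diagram <- function(diagram) {
  if (attr(diagram, "log_scaled")) return(diagram)
  if (any(diagram$birth <= 0 | diagram$death <= 0)) {
    stop("log scaling requires strictly positive births and deaths; ",
         "this diagram contains non-positive values", call. = FALSE)
  }
  diagram$birth <- log(diagram$birth)
  diagram$death <- log(diagram$death)
  attr(diagram, "log_scaled") <- TRUE
  diagram
}

#' Persistence diagram of an image under a named filtration
#'
#' Convenience wrapper chaining [preprocess_image()], [compute_filtration()],
#' [compute_persistence()] and, for the kNN density, [log_scale_diagram()].
#'
#' @inheritParams compute_filtration
#' @param image a raster accepted by [to_grayscale()].
#' @param config a [preprocess_config()].
#' @param log_scale whether to log-scale (default: only for `"knn"`).
#' @return a `persistence_diagram`.
#' @export
image_persistence <- function(image, filtration = c("knn", "signed", "gray"),
                              config = preprocess_config(trim_width = NULL),
                              k = 100, spacing = 10, log_scale = NULL) {
  filtration <- match.arg(filtration)
  if (is.null(log_scale)) log_scale <- filtration == "knn"
  prep <- preprocess_image(image, config)
  fld <- compute_filtration(prep, filtration, k = k, spacing = spacing)
  d <- compute_persistence(fld)
  if (log_scale) d <- log_scale_diagram(d) else d
}
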