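#' Synthetic skin texture parameters
#'
#' The generator emulates the micro-relief of cheek skin as seen by a digital
#' microscope after binarization: a *bright* network of sulci (furrows) drawn
#' as the boundaries of a Voronoi partition over a jittered hexagonal lattice
#' of cell sites, enclosing darker cristae (ridge plateaus). `jitter` is the
#' regularity dial: 0 gives a periodic honeycomb (regular texture, many holes
#' appearing convergently), values toward 1 give increasingly irregular cell
#' sizes and a loose hole distribution, mimicking rough, barrier-impaired
#' skin. A linear brightness gradient and Gaussian pixel noise emulate uneven
#' illumination and sensor noise.
#'
#' @param width,height frame size in pixels (default 700 x 600, half the
#'   microscope frame used at full scale).
#' @param cell_pitch lattice spacing in pixels (default 40).
#' @param jitter site displacement standard deviation as a fraction of
#'   `cell_pitch`, in \[0, 1\].
#' @param ridge_width sulcus line width in pixels (default 6; the invariant
#'   `cell_pitch >= 4 * ridge_width` keeps cells open).
#' @param brightness_gradient intensity span of the left-to-right illumination
#'   gradient (default 30).
#' @param noise_sd Gaussian pixel noise standard deviation (default 8).
#' @param seed optional integer for reproducibility.
#' @return a `texture_params` list.
#' @export
texture_params <- function(width = 700, height = 600, cell_pitch = 40,
                           jitter = 0, ridge_width = 6,
                           brightness_gradient = 30, noise_sd = 8,
                           seed = NULL) {
  if (jitter < 0 || jitter > 1) stop("jitter must lie in [0, 1]", call. = FALSE)
  if (cell_pitch < 4 * ridge_width) {
    stop("cell_pitch must be at least 4 * ridge_width", call. = FALSE)
  }
  structure(list(width = width, height = height, cell_pitch = cell_pitch,
                 jitter = jitter, ridge_width = ridge_width,
                 brightness_gradient = brightness_gradient,
                 noise_sd = noise_sd, seed = seed),
            class = "texture_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic skin texture
#'
#' See [texture_params()] for the model. Deterministic under a fixed seed.
#'
#' @param params a [texture_params()].
#' @return a [gray_image][as_gray_image] of `height` x `width` pixels.
#' @examples
#' img <- generate_texture(texture_params(width = 200, height = 180, seed = 1))
#' @export
generate_texture <- function(params) {
  stopifnot(inherits(params, "texture_params"))
  with_seed(params$seed, {
    p <- params
    dy <- p$cell_pitch * sqrt(3) / 2
    ys <- seq(-p$cell_pitch, p$height + p$cell_pitch, by = dy)
    centers <- do.call(rbind, lapply(seq_along(ys), function(i) {
      off <- if (i %% 2 == 0) p$cell_pitch / 2 else 0
      xs <- seq(-p$cell_pitch + off, p$width + p$cell_pitch, by = p$cell_pitch)
      cbind(ys[i], xs)
    }))
    if (p$jitter > 0) {
      centers <- centers + matrix(rnorm(length(centers), sd = p$jitter * p$cell_pitch),
                                  ncol = 2)
    }
    px <- cbind(rep(seq_len(p$height), times = p$width),
                rep(seq_len(p$width), each = p$height))
    nn <- FNN::get.knnx(centers, px, k = 2)
    # the Voronoi boundary band: equidistant from the two nearest sites
    ridge <- (nn$nn.dist[, 2] - nn$nn.dist[, 1]) < p$ridge_width
    base <- ifelse(ridge, 190, 70)
    img <- matrix(base, nrow = p$height, ncol = p$width)
    if (p$brightness_gradient != 0) {
      grad <- p$brightness_gradient * (seq_len(p$width) - 1) / (p$width - 1)
      img <- img + matrix(grad - p$brightness_gradient / 2,
                          nrow = p$height, ncol = p$width, byrow = TRUE)
    }
    if (p$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), sd = p$noise_sd), nrow = p$height)
    }
    m <- round(pmin(pmax(img, 0), 255))
    storage.mode(m) <- "integer"
    as_gray_image(m)
  })
}

#' Synthetic cohort specification
#'
#' Defines a cohort in which each subject's texture regularity (the `jitter`
#' parameter) generatively drives transepidermal water loss:
#' `tewl = intercept + slope * jitter + Normal(0, tewl_sd)`, floored at
#' 1 g m^-2 h^-1. Defaults give cheek-like TEWL between roughly 8 and 35.
#' Covariates mirror the study population: age uniform on 0--64 years, sex
#' Bernoulli(0.5) coded 0/1 (F/M), and the controlled test room's temperature
#' (20.0 C) and humidity (50%) with small spread. Stratum-corneum moisture
#' readings (Corneometer a.u., Skicon micro-Siemens) are generated with a
#' weaker, partly environmental link, mirroring their weaker association with
#' texture.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param images_per_subject images per subject and session (default 3).
#' @param jitter_range range the per-subject jitter is drawn from.
#' @param tewl_intercept,tewl_slope,tewl_sd generative TEWL link
#'   (g m^-2 h^-1; defaults 8, 25, 3).
#' @param texture a [texture_params()] template (its jitter/seed are
#'   overridden per image).
#' @param seed integer seed; the whole cohort is a pure function of the spec.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 40, images_per_subject = 3,
                        jitter_range = c(0, 0.8),
                        tewl_intercept = 8, tewl_slope = 25, tewl_sd = 3,
                        texture = texture_params(), seed = 1) {
  if (n_subjects < 4) stop("n_subjects must be >= 4", call. = FALSE)
  if (tewl_sd <= 0) stop("tewl_sd must be > 0", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 images_per_subject = images_per_subject,
                 jitter_range = jitter_range,
                 tewl_intercept = tewl_intercept, tewl_slope = tewl_slope,
                 tewl_sd = tewl_sd, texture = texture, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject jitter and TEWL per [cohort_spec()], renders
#' `images_per_subject` textures per subject (each with its own sub-seed), and
#' assembles the cohort table linking images to responses and covariates.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `images` (named list of [gray_image][as_gray_image])
#'   and `cohort`, a tibble keyed by `(subject_id, session, image_index)` with
#'   columns `image_id`, `tewl`, `moisture_corneometer`, `moisture_skicon`,
#'   `age`, `sex`, `temperature`, `humidity`, `site`, and the generator truth
#'   `jitter`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    jit <- runif(n, spec$jitter_range[1], spec$jitter_range[2])
    tewl <- pmax(spec$tewl_intercept + spec$tewl_slope * jit +
                   rnorm(n, sd = spec$tewl_sd), 1)
    age <- runif(n, 0, 64)
    sex <- stats::rbinom(n, 1, 0.5)
    temperature <- rnorm(n, 20, 0.5)
    humidity <- rnorm(n, 50, 3)
    corneo <- 65 - 0.8 * tewl + 0.3 * (humidity - 50) + rnorm(n, sd = 5)
    skicon <- pmax(260 - 6 * tewl + 2.5 * (humidity - 50) + rnorm(n, sd = 25), 5)
    img_seeds <- sample.int(.Machine$integer.max - 1L,
                            n * spec$images_per_subject)

    rows <- list(); images <- list(); r <- 0L
    for (s in seq_len(n)) {
      for (i in seq_len(spec$images_per_subject)) {
        r <- r + 1L
        id <- sprintf("s%03d_1_%d", s, i)
        tp <- spec$texture
        tp$jitter <- jit[s]
        tp$seed <- img_seeds[r]
        images[[id]] <- generate_texture(tp)
        rows[[r]] <- tibble::tibble(
          image_id = id, subject_id = sprintf("s%03d", s), session = 1L,
          image_index = i, tewl = tewl[s],
          moisture_corneometer = corneo[s], moisture_skicon = skicon[s],
          age = age[s], sex = sex[s], temperature = temperature[s],
          humidity = humidity[s], site = "left_cheek", jitter = jit[s])
      }
    }
    list(images = images, cohort = dplyr::bind_rows(rows))
  })
}
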