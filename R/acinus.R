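#' Geometry of the starting prostatic acinus
#'
#' The healthy acinus is rasterized as a Euclidean disk of empty lumen
#' (radius `lumen_radius` grid spaces) surrounded by four concentric
#' one-space rings grown by successive Chebyshev dilations: luminal cells
#' (containing a fraction of stem cells), basal cells, basement membrane
#' (passive) and tissue-resident fibroblasts. Everything beyond the rings
#' is stroma: extracellular matrix laid down at density `ecm_density`,
#' with additional fibroblasts sprinkled at `ecm_fibroblast_density`, and
#' interstitial empty spaces through which macrophages can travel.
#' Macrophages enter from a 2 x 2 block in the top-left corner,
#' representing a blood vessel.
#'
#' @param width,height grid dimensions.
#' @param center 0-based `c(row, col)` of the acinus center; defaults to
#'   the grid center.
#' @param lumen_radius lumen radius in grid spaces (default 13).
#' @param axis_ratio row/column axis ratio of the lumen (1 = circle).
#' @param stem_fraction_luminal fraction of initial luminal ring cells
#'   that are stem cells.
#' @param fibro_ring_density fraction of fibroblast-layer positions
#'   holding a resident fibroblast; the interstitial gaps let macrophages
#'   hop over the basement membrane into the epithelium.
#' @param ecm_density fraction of stromal positions carrying ECM.
#' @param ecm_fibroblast_density fraction of stromal positions holding a
#'   fibroblast.
#' @return A list of class `acinus_geometry`.
#' @export
acinus_geometry <- function(width = 125L, height = 125L, center = NULL,
                            lumen_radius = 13L, axis_ratio = 1,
                            stem_fraction_luminal = 0.05,
                            fibro_ring_density = 0.6,
                            ecm_density = 0.45,
                            ecm_fibroblast_density = 0.15) {
  if (is.null(center)) center <- c(height %/% 2L, width %/% 2L)
  structure(list(width = as.integer(width), height = as.integer(height),
                 center = as.integer(center),
                 lumen_radius = as.integer(lumen_radius),
                 axis_ratio = axis_ratio,
                 stem_fraction_luminal = stem_fraction_luminal,
                 fibro_ring_density = fibro_ring_density,
                 ecm_density = ecm_density,
                 ecm_fibroblast_density = ecm_fibroblast_density),
            class = "acinus_geometry")
}

# ring codes: 0 lumen, 1 luminal, 2 basal, 3 BM, 4 fibroblast layer, 5 ECM
region_codes <- function() {
  c(lumen = 0L, luminal = 1L, basal = 2L, bm = 3L, fibroblast = 4L,
    ecm = 5L)
}

# Chebyshev dilation of a logical mask by one grid space
dilate1 <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(h, h + dr)
    rt <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    ct <- max(1, 1 - dc):min(w, w - dc)
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}

#' Ring-code matrix of an acinus geometry
#'
#' @param geometry an [acinus_geometry()].
#' @return Integer matrix of codes 0 (lumen) to 5 (ECM), see
#'   [region_codes()].
#' @export
acinus_region_code <- function(geometry) {
  h <- geometry$height
  w <- geometry$width
  cr <- geometry$center[1]
  cc <- geometry$center[2]
  r <- matrix(0:(h - 1), h, w)
  c_ <- matrix(0:(w - 1), h, w, byrow = TRUE)
  d <- sqrt(((r - cr) * geometry$axis_ratio)^2 + (c_ - cc)^2)
  lumen <- d < geometry$lumen_radius
  if (!any(lumen)) stop("lumen radius too small for this grid")
  code <- matrix(region_codes()[["ecm"]], h, w)
  acc <- lumen
  rings <- c("luminal", "basal", "bm", "fibroblast")
  code[lumen] <- region_codes()[["lumen"]]
  for (ring in rings) {
    grown <- dilate1(acc)
    band <- grown & !acc
    if (!any(band)) stop("acinus rings exceed the grid")
    code[band] <- region_codes()[[ring]]
    acc <- grown
  }
  if (any(acc[c(1, h), ]) || any(acc[, c(1, w)]))
    stop("acinus rings exceed the grid")
  code
}

#' Build the healthy-acinus starting state
#'
#' @param geometry an [acinus_geometry()].
#' @param params an `abm_params` list (division budgets of the seeded
#'   epithelium are taken from it).
#' @return A `grid_state` with zero tumor cells, CAFs and macrophages:
#'   closed luminal/basal cell rings (with `stem_fraction_luminal` stem
#'   cells at random luminal positions), an intact basement-membrane ring,
#'   a fibroblast ring, and stroma of ECM plus sprinkled fibroblasts.
#'   Uses the current RNG state (call `set.seed()` upstream).
#' @export
build_acinus <- function(geometry = acinus_geometry(),
                         params = default_parameters()) {
  code <- acinus_region_code(geometry)
  h <- geometry$height
  w <- geometry$width
  rc <- region_codes()
  passive <- matrix(0L, h, w)
  passive[code == rc[["bm"]]] <- 1L

  # stroma: ECM at ecm_density, fibroblasts at ecm_fibroblast_density,
  # remainder interstitial empty space (lets macrophages percolate)
  stroma <- which(code == rc[["ecm"]])
  entry <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  entry_idx <- entry[, 1] + 1L + entry[, 2] * h  # column-major index
  stroma <- setdiff(stroma, entry_idx)
  u <- runif(length(stroma))
  fib_stroma <- stroma[u < geometry$ecm_fibroblast_density]
  ecm_pos <- stroma[u >= geometry$ecm_fibroblast_density &
                    u < geometry$ecm_fibroblast_density +
                        geometry$ecm_density]
  passive[ecm_pos] <- 2L

  lum_pos <- which(code == rc[["luminal"]])
  bas_pos <- which(code == rc[["basal"]])
  fib_ring <- which(code == rc[["fibroblast"]])
  keep <- runif(length(fib_ring)) < geometry$fibro_ring_density
  fib_ring <- fib_ring[keep]
  n_stem <- round(length(lum_pos) * geometry$stem_fraction_luminal)
  stem_pos <- if (n_stem > 0) sample(lum_pos, n_stem) else integer()

  make <- function(idx, kind, div) {
    if (!length(idx)) return(empty_agents())
    data.frame(id = 0L, kind = kind, row = (idx - 1L) %% h,
               col = (idx - 1L) %/% h, mutations = 0L,
               divisions_left = div, kills_left = 0L, emt = FALSE,
               age = 0L, stringsAsFactors = FALSE)
  }
  agents <- rbind(
    make(setdiff(lum_pos, stem_pos), "luminal", params$TUpmax),
    make(stem_pos, "stem", Inf),
    make(bas_pos, "basal", params$TUpmax),
    make(fib_ring, "fibroblast", Inf),
    make(fib_stroma, "fibroblast", Inf))
  agents$id <- seq_len(nrow(agents))

  # physiologic regions, frozen from the initial geometry: luminal cells
  # may also fill lumen positions bordering their ring; basal cells are
  # confined to the basal ring
  lum_ring_mask <- code == rc[["luminal"]]
  lum_region <- (dilate1(lum_ring_mask) & code == rc[["lumen"]]) |
    lum_ring_mask
  bas_region <- code == rc[["basal"]]

  new_grid_state(width = w, height = h, agents = agents, passive = passive,
                 luminal_region = lum_region, basal_region = bas_region,
                 region_code = code, entry = entry)
}

#' Configuration of the acinus model
#'
#' @param params an `abm_params` list.
#' @param geometry an [acinus_geometry()].
#' @param n_steps simulated steps (default 800 = 400 days at 12 h/step).
#' @param record_every,record_events see [simulate_steps()].
#' @return A list of class `acinus_config`.
#' @export
acinus_config <- function(params = default_parameters(),
                          geometry = acinus_geometry(), n_steps = 800L,
                          record_every = 8L, record_events = FALSE) {
  structure(list(params = params, geometry = geometry,
                 n_steps = as.integer(n_steps),
                 record_every = as.integer(record_every),
                 record_events = isTRUE(record_events)),
            class = "acinus_config")
}

#' Simulate prostate cancer onset and progression in one acinus
#'
#' Builds the healthy acinus, iterates the scheduler for `n_steps` steps
#' and records population time series (per-kind counts, stem percentage,
#' mean mutation load of mutated cells, M2:M1 ratio, remaining
#' basement-membrane positions) plus milestone steps: first mutation,
#' first tumor occupancy of the basal layer, first CAF, first M2
#' macrophage, basement-membrane breakdown (first destroyed BM position —
#' the cancer marker), first EMT and first tumor cell outside the
#' basement-membrane ring.
#'
#' @param config an [acinus_config()].
#' @param seed integer seed.
#' @return An `abm_result` with additional fields `tumor_load_400d`
#'   (mutated cells at the final step) and `developed_cancer` (whether
#'   the basement membrane was breached).
#' @export
run_acinus <- function(config = acinus_config(), seed = NULL) {
  stopifnot(inherits(config, "acinus_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- build_acinus(config$geometry, config$params)
  res <- simulate_steps(state, config$params, config$n_steps,
                        model = "acinus",
                        record_every = config$record_every,
                        record_events = config$record_events)
  last <- res$timeseries[nrow(res$timeseries), ]
  res$tumor_load_400d <- last$n_mutated
  res$developed_cancer <- !is.na(res$milestones[["bm_breakdown"]])
  res$config <- config
  res$seed <- seed
  res
}

#' Run a batch of acinus simulations with derived child seeds
#'
#' Replicate `i` runs with seed `base_seed + i`, making batches
#' reproducible and extendable.
#'
#' @param config an [acinus_config()].
#' @param n_runs number of replicates.
#' @param base_seed integer; replicate seeds are `base_seed + 1:n_runs`.
#' @param keep_state keep each final `grid_state` (memory-heavy).
#' @return A list of `abm_result` objects of class `abm_batch`.
#' @export
run_acinus_batch <- function(config = acinus_config(), n_runs = 10L,
                             base_seed = 0L, keep_state = FALSE) {
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    res <- run_acinus(config, seed = base_seed + i)
    if (!keep_state) res$state <- NULL
    out[[i]] <- res
  }
  class(out) <- "abm_batch"
  out
}
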