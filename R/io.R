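#' Load a simulation configuration from a structured text file
#'
#' Configurations are YAML with up to three sections: `parameters` (any
#' subset of [default_parameters()]), `geometry` (fields of
#' [acinus_geometry()]) and `run` (`model`, `n_steps`, `seed`,
#' `record_every`, plus the minimal-model fields `scenario`, `n_seed`,
#' `sc_start`, `pmut`). Unknown sections or keys are an error naming the
#' offender; omitted keys resolve to package defaults and the returned
#' object records per-field provenance (`"default"` vs `"user"`).
#'
#' @param path path to a YAML file; an empty file yields the full-default
#'   configuration.
#' @return A list of class `sim_config` with elements `model`, `params`,
#'   `geometry`, `run` and attribute `provenance`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  known_sections <- c("parameters", "geometry", "run")
  bad <- setdiff(names(raw), known_sections)
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  build_config(raw$parameters, raw$geometry, raw$run)
}

build_config <- function(parameters = NULL, geometry = NULL, run = NULL) {
  defaults_p <- unclass(default_parameters())
  if (!is.null(parameters)) {
    bad <- setdiff(names(parameters), names(defaults_p))
    if (length(bad)) stop("unknown parameter key(s): ",
                          paste(bad, collapse = ", "))
  }
  p <- modifyList(defaults_p, as.list(parameters))
  p <- normalize_parameters(p)
  validate_parameters(p)
  class(p) <- "abm_params"

  geo_defaults <- unclass(acinus_geometry())
  if (!is.null(geometry)) {
    bad <- setdiff(names(geometry), names(geo_defaults))
    if (length(bad)) stop("unknown geometry key(s): ",
                          paste(bad, collapse = ", "))
  }
  geo <- modifyList(geo_defaults, as.list(geometry))
  geo <- do.call(acinus_geometry, geo)

  run_defaults <- list(model = "acinus", n_steps = 800L, seed = 1L,
                       record_every = 8L, scenario = "combined",
                       n_seed = 1500L, sc_start = NULL, pmut = NULL)
  if (!is.null(run)) {
    bad <- setdiff(names(run), names(run_defaults))
    if (length(bad)) stop("unknown run key(s): ",
                          paste(bad, collapse = ", "))
  }
  rn <- modifyList(run_defaults, as.list(run))
  if (!rn$model %in% c("minimal", "acinus"))
    stop("run$model must be 'minimal' or 'acinus'")
  if (rn$n_steps < 1) stop("run$n_steps must be >= 1")

  prov <- list(
    parameters = setNames(
      ifelse(names(defaults_p) %in% names(parameters), "user", "default"),
      names(defaults_p)),
    geometry = setNames(
      ifelse(names(geo_defaults) %in% names(geometry), "user", "default"),
      names(geo_defaults)),
    run = setNames(
      ifelse(names(run_defaults) %in% names(run), "user", "default"),
      names(run_defaults)))
  structure(list(model = rn$model, params = p, geometry = geo, run = rn),
            class = "sim_config", provenance = prov)
}

#' Save a simulation configuration
#'
#' Writes the full resolved configuration; [load_config()] on the result
#' reproduces the configuration exactly.
#'
#' @param config a `sim_config` from [load_config()] or [build_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  rn <- config$run[!vapply(config$run, is.null, logical(1))]
  out <- list(parameters = unclass(config$params),
              geometry = unclass(config$geometry), run = rn)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

# published integer code table for grid snapshots
snapshot_codes <- function() {
  c(empty = 0L, basement_membrane = 1L, ecm = 2L, luminal = 3L,
    basal = 4L, stem = 5L, tumor = 6L, fibroblast = 7L, caf = 8L,
    m1 = 9L, m2 = 10L)
}

#' Encode a grid state as an integer-coded matrix
#'
#' One code per grid space: 0 empty, 1 basement membrane, 2 ECM, then the
#' agent kinds 3 luminal, 4 basal, 5 stem, 6 tumor, 7 fibroblast, 8 CAF,
#' 9 M1, 10 M2. The encoding is lossless for kinds and passive layers but
#' drops per-cell counters (mutations, remaining divisions/kills, EMT).
#'
#' @param state a `grid_state`.
#' @return Integer matrix (`height` x `width`).
#' @export
encode_grid <- function(state) {
  m <- state$passive  # empty/BM/ECM codes coincide
  a <- state$agents
  if (nrow(a))
    m[cbind(a$row + 1L, a$col + 1L)] <-
      snapshot_codes()[a$kind]
  m
}

#' Decode an integer-coded matrix into a skeleton grid state
#'
#' Inverse of [encode_grid()] up to per-cell counters: agents are restored
#' with default counters (zero mutations, `NA`-free defaults), passive
#' layers exactly.
#'
#' @param m integer-coded matrix.
#' @return A `grid_state`.
#' @export
decode_grid <- function(m) {
  codes <- snapshot_codes()
  passive <- matrix(0L, nrow(m), ncol(m))
  passive[m == codes[["basement_membrane"]]] <- 1L
  passive[m == codes[["ecm"]]] <- 2L
  agent_codes <- codes[kind_levels()]
  idx <- which(m %in% agent_codes)
  kind <- kind_levels()[match(m[idx], agent_codes)]
  agents <- if (length(idx)) {
    data.frame(id = seq_along(idx), kind = kind,
               row = (idx - 1L) %% nrow(m), col = (idx - 1L) %/% nrow(m),
               mutations = 0L,
               divisions_left = ifelse(kind == "stem", Inf, 1),
               kills_left = 0L, emt = FALSE, age = 0L,
               stringsAsFactors = FALSE)
  } else empty_agents()
  new_grid_state(width = ncol(m), height = nrow(m), agents = agents,
                 passive = passive)
}

#' Default rendering palette
#'
#' @return Named vector of colors per snapshot code name.
#' @export
default_palette <- function() {
  c(empty = "#FFFFFF", basement_membrane = "#555555", ecm = "#E8DCC8",
    luminal = "#1F77B4", basal = "#9EDAE5", stem = "#FFD700",
    tumor = "#D62728", fibroblast = "#2CA02C", caf = "#8C564B",
    m1 = "#17BECF", m2 = "#E377C2")
}

#' Render a grid snapshot
#'
#' Always produces the integer-coded matrix; optionally writes it as CSV
#' and renders a PNG image (one `scale` x `scale` pixel block per grid
#' space, empty space rendered white).
#'
#' @param state a `grid_state`.
#' @param png_file optional path of the PNG to write.
#' @param csv_file optional path of the coded-matrix CSV to write.
#' @param palette named colors per code name (see [default_palette()]).
#' @param scale pixels per grid space.
#' @return The coded matrix, invisibly.
#' @export
render_snapshot <- function(state, png_file = NULL, csv_file = NULL,
                            palette = default_palette(), scale = 4L) {
  m <- encode_grid(state)
  if (!is.null(csv_file))
    write.table(m, csv_file, sep = ",", row.names = FALSE,
                col.names = FALSE)
  if (!is.null(png_file)) {
    cols <- palette[names(snapshot_codes())]
    rgbm <- grDevices::col2rgb(cols) / 255
    h <- nrow(m)
    w <- ncol(m)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3)
      img[, , ch] <- matrix(rgbm[ch, m + 1L], h, w)
    if (scale > 1L) {
      img <- img[rep(seq_len(h), each = scale),
                 rep(seq_len(w), each = scale), , drop = FALSE]
    }
    png::writePNG(img, png_file)
  }
  invisible(m)
}

#' Write the standard output files of a simulation run
#'
#' `timeseries.csv` (per-step population counts and summary columns),
#' `milestones.csv` (milestone, step, days) and, when the run kept its
#' event log, `events.tsv`.
#'
#' @param result an `abm_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$timeseries, file.path(dir, "timeseries.csv"),
            row.names = FALSE)
  ms <- data.frame(milestone = names(result$milestones),
                   step = as.integer(result$milestones),
                   days = as.numeric(result$milestones) / 2)
  write.csv(ms, file.path(dir, "milestones.csv"), row.names = FALSE)
  if (!is.null(result$events))
    write.table(result$events, file.path(dir, "events.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(dir)
}
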