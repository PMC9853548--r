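# Run configuration: one flat key/value set shared by all pipeline stages.
# Defaults carry the method's operating constants (contour expansion 5 px,
# RDP epsilon 1.5, fingerprint buffering 10 x (3x3) dilation + 7x7 blur,
# quarter-scale resize, 6 cm proximity threshold, 60 Hz, 32 cm arena).

mt_default_config <- function() {
  list(
    n_mice          = NA_integer_,
    # arena / recording
    arena_cm        = 32,
    arena_px        = 640,
    fps             = 60,
    # segmentation
    threshold_mode  = "fixed",   # "fixed" or "otsu"
    threshold       = 160,
    min_area_px     = 500,
    max_area_px     = Inf,
    expand_px       = 5,
    rdp_epsilon     = 1.5,
    # fingerprint
    dilation_iters  = 10,
    dilation_kernel = 3,
    blur_kernel     = 7,
    downscale       = 4,
    n_dist_bins     = 32,
    n_sum_bins      = 32,
    max_dist_px     = 64,
    max_pairs       = Inf,
    # correction
    max_gap         = 60,
    # analysis
    proximity_cm    = 6.0,
    # reproducibility / synthetic stage
    seed            = 1,
    n_frames        = NA_integer_,
    frames_dir      = NA_character_,
    masks_from      = NA_character_,
    swaps_csv       = NA_character_
  )
}

mt_string_keys <- c("threshold_mode", "frames_dir", "masks_from", "swaps_csv")

#' Build or load a run configuration
#'
#' `mt_config()` builds a validated configuration from defaults plus
#' overrides; `load_config()` reads one from a flat `key = value` text file
#' (`#` comments and blank lines ignored). Missing keys take the pipeline
#' defaults; `n_mice` is required.
#'
#' @param path Path to a flat key/value text file.
#' @param ... Named overrides of default keys (e.g. `n_mice = 2`,
#'   `proximity_cm = 4.5`).
#' @return A validated list of class `mt_config`.
#' @examples
#' cfg <- mt_config(n_mice = 2)
#' cfg$rdp_epsilon # 1.5
#' @export
mt_config <- function(...) {
  cfg <- mt_default_config()
  ov <- list(...)
  if (length(ov) && (is.null(names(ov)) || any(names(ov) == "")))
    stop("config error: all overrides must be named")
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in intersect(names(ov), names(cfg))) cfg[[k]] <- ov[[k]]
  validate_config(cfg)
}

#' @rdname mt_config
#' @export
load_config <- function(path, ...) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config error: expected 'key = value', got: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- if (key %in% mt_string_keys) val else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("config error: non-numeric value for key '", key,
                           "': ", val)
      num
    }
  }
  do.call(mt_config, c(kv, list(...)))
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config error: ", msg, call. = FALSE)
  chk(!is.na(cfg$n_mice) && is.numeric(cfg$n_mice) && cfg$n_mice >= 1 &&
        cfg$n_mice == round(cfg$n_mice), "n_mice must be an integer >= 1")
  cfg$n_mice <- as.integer(cfg$n_mice)
  odd <- function(k) k >= 1 && k == round(k) && k %% 2 == 1
  chk(odd(cfg$dilation_kernel), "dilation_kernel must be odd and >= 1")
  chk(odd(cfg$blur_kernel), "blur_kernel must be odd and >= 1")
  chk(cfg$downscale >= 1 && cfg$downscale == round(cfg$downscale),
      "downscale must be an integer >= 1")
  chk(cfg$dilation_iters >= 0, "dilation_iters must be >= 0")
  chk(cfg$n_dist_bins >= 2 && cfg$n_sum_bins >= 2, "bin counts must be >= 2")
  chk(cfg$max_dist_px > 0, "max_dist_px must be > 0")
  chk(cfg$expand_px >= 0, "expand_px must be >= 0")
  chk(cfg$rdp_epsilon >= 0, "rdp_epsilon must be >= 0")
  chk(cfg$min_area_px >= 0 && cfg$min_area_px < cfg$max_area_px,
      "need 0 <= min_area_px < max_area_px")
  chk(cfg$threshold_mode %in% c("fixed", "otsu"),
      "threshold_mode must be 'fixed' or 'otsu'")
  chk(cfg$proximity_cm > 0, "proximity_cm must be > 0")
  chk(cfg$fps > 0, "fps must be > 0")
  chk(cfg$arena_cm > 0 && cfg$arena_px > 0, "arena sizes must be > 0")
  chk(cfg$max_gap >= 0, "max_gap must be >= 0")
  structure(cfg, class = "mt_config")
}

#' @export
print.mt_config <- function(x, ...) {
  cat("mousetrackr run configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.character(v) && is.na(v)) next
    cat(sprintf("  %-16s %s\n", k, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# Parameter-block views used by the stage functions.
seg_params_from_config <- function(cfg) {
  segmentation_params(
    threshold_mode = cfg$threshold_mode, threshold = cfg$threshold,
    min_area_px = cfg$min_area_px, max_area_px = cfg$max_area_px,
    expand_px = cfg$expand_px, rdp_epsilon = cfg$rdp_epsilon
  )
}

fp_params_from_config <- function(cfg) {
  fingerprint_params(
    dilation_iters = cfg$dilation_iters, dilation_kernel = cfg$dilation_kernel,
    blur_kernel = cfg$blur_kernel, downscale = cfg$downscale,
    n_dist_bins = cfg$n_dist_bins, n_sum_bins = cfg$n_sum_bins,
    max_dist_px = cfg$max_dist_px, max_pairs = cfg$max_pairs, seed = cfg$seed
  )
}
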