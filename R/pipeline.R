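#' Run configuration for the analysis pipeline
#'
#' Collects every tunable of the photographic and laser workflows with the
#' conventional defaults: gamma 2.2 with all RGB bands, five 15-degree
#' annuli, equidistant lens, truncation-corrected Miller inversion,
#' species STAR values of 0.147 (pine) and 0.161 (spruce, with broadleaves
#' uncorrected), and a 10 m cylinder / 50 levels / 1.5 m ground cut for
#' the laser proxy.
#'
#' @param lens A [lens_function()].
#' @param out_size Hemispherical image size, pixels.
#' @param gamma,channel_mode,threshold_mode,manual_threshold Passed to
#'   [segmentation_config()].
#' @param n_annuli,annulus_width_deg Passed to [annulus_set()].
#' @param star Optional STAR for shoot clumping correction (`NULL` = none).
#' @param truncation_correct,clip_negative Analysis flags.
#' @param als_radius,als_levels,als_ground_cut Laser-proxy settings.
#' @param seed Integer seed for any stochastic step.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(lens = lens_function(), out_size = 2000,
                       gamma = 2.2, channel_mode = "rgb_mean",
                       threshold_mode = "ridler_calvard",
                       manual_threshold = 0.5,
                       n_annuli = 5, annulus_width_deg = 15,
                       star = NULL, truncation_correct = TRUE,
                       clip_negative = FALSE,
                       als_radius = 10, als_levels = 50, als_ground_cut = 1.5,
                       seed = 1L) {
  structure(list(lens = lens, out_size = out_size,
                 seg = segmentation_config(gamma = gamma,
                                           channel_mode = channel_mode,
                                           threshold_mode = threshold_mode,
                                           manual_threshold = manual_threshold),
                 annuli = annulus_set(n_annuli, annulus_width_deg),
                 star = star, truncation_correct = truncation_correct,
                 clip_negative = clip_negative,
                 als = list(radius = als_radius, levels = als_levels,
                            ground_cut = als_ground_cut),
                 seed = seed),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' Round-trips through a plain YAML file so a run can be reproduced from
#' its provenance record.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return [write_run_config()]: `path`, invisibly. [read_run_config()]:
#'   a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  flat <- list(lens = unclass(cfg$lens), out_size = cfg$out_size,
               gamma = cfg$seg$gamma, channel_mode = cfg$seg$channel_mode,
               threshold_mode = cfg$seg$threshold_mode,
               manual_threshold = cfg$seg$manual_threshold,
               n_annuli = cfg$annuli$n_annuli,
               annulus_width_deg = cfg$annuli$width_deg,
               star = cfg$star, truncation_correct = cfg$truncation_correct,
               clip_negative = cfg$clip_negative, als = cfg$als,
               seed = cfg$seed)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  f <- yaml::read_yaml(path)
  run_config(lens = lens_function(f$lens$kind, f$lens$coefficients,
                                  f$lens$theta_max),
             out_size = f$out_size, gamma = f$gamma,
             channel_mode = f$channel_mode, threshold_mode = f$threshold_mode,
             manual_threshold = f$manual_threshold, n_annuli = f$n_annuli,
             annulus_width_deg = f$annulus_width_deg, star = f$star,
             truncation_correct = f$truncation_correct,
             clip_negative = f$clip_negative,
             als_radius = f$als$radius, als_levels = f$als$levels,
             als_ground_cut = f$als$ground_cut, seed = f$seed)
}

#' Analyze one panorama: reproject, segment, invert to PAI
#'
#' @param pano A [panorama()].
#' @param cfg A [run_config()].
#' @return One-row data frame: threshold used, per-annulus gap fractions
#'   (`P_1` ...), `pai_raw`, `pai_corrected` (`NA` without a STAR).
#' @export
analyze_panorama <- function(pano, cfg = run_config()) {
  hemi <- reproject_to_hemisphere(pano, out_size = cfg$out_size,
                                  lens = cfg$lens)
  mask <- segment_image(hemi, cfg$seg)
  gp <- gap_fractions(mask, cfg$annuli, cfg$lens)
  est <- miller_pai(gp, truncation_correct = cfg$truncation_correct,
                    star = cfg$star)
  row <- data.frame(threshold = mask$threshold, t(gp$P),
                    pai_raw = est$pai_raw,
                    pai_corrected = est$pai_clumping_corrected)
  names(row)[2:(1 + length(gp$P))] <- paste0("P_", seq_along(gp$P))
  row
}

#' Run the full photographic workflow over a file manifest
#'
#' Reads each panorama, runs reproject -> segment -> gap fractions ->
#' Miller PAI, and (when capture heights are given) aggregates the rows
#' into a vertical PAI/PAD profile. Results and a machine-readable
#' provenance record (configuration, per-image thresholds, package
#' version) are written to `out_dir`. Processing stops at the first stage
#' error, naming the offending file.
#'
#' @param files Character vector of panorama paths (PNG/TIFF).
#' @param cfg A [run_config()].
#' @param heights Optional numeric vector, one capture height per file;
#'   enables the profile stage.
#' @param out_dir Output directory (`NULL` skips writing).
#' @return List: `images` (per-image results data frame), `profile` (a
#'   [height_profile()] or `NULL`).
#' @export
run_pipeline <- function(files, cfg = run_config(), heights = NULL,
                         out_dir = NULL) {
  if (!is.null(heights)) stopifnot(length(heights) == length(files))
  rows <- lapply(seq_along(files), function(i) {
    row <- tryCatch({
      pano <- read_panorama(files[i])
      analyze_panorama(pano, cfg)
    }, error = function(e) {
      stop(sprintf("pipeline failed at '%s': %s", files[i], conditionMessage(e)),
           call. = FALSE)
    })
    cbind(data.frame(file = basename(files[i]),
                     height = if (is.null(heights)) NA_real_ else heights[i]),
          row)
  })
  images <- do.call(rbind, rows)
  profile <- NULL
  if (!is.null(heights) && length(unique(heights)) >= 2) {
    profile <- height_profile(data.frame(height = images$height,
                                         pai = images$pai_raw),
                              clip_negative = cfg$clip_negative)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(images, file.path(out_dir, "images.csv"),
                     row.names = FALSE)
    if (!is.null(profile)) {
      utils::write.csv(data.frame(height = profile$heights,
                                  pai_mean = profile$pai,
                                  deviation_pct = profile$deviation_pct),
                       file.path(out_dir, "profile_pai.csv"), row.names = FALSE)
      utils::write.csv(profile$layers, file.path(out_dir, "profile_pad.csv"),
                       row.names = FALSE)
    }
    write_run_config(cfg, file.path(out_dir, "config.yaml"))
    prov <- list(package_version = as.character(utils::packageVersion("canopysphere")),
                 files = basename(files),
                 thresholds = images$threshold, seed = cfg$seed)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(images = images, profile = profile)
}
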