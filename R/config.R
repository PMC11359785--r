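# Structured-text configuration round trip for the parameter objects.
# Keys carry explicit units; YAML and JSON dialects are both accepted
# (chosen by file extension).

pk_key_map <- c(
  fu = "fu_fraction", bp_ratio = "bp_ratio",
  fu_mic = "fu_mic_fraction",
  clint_u_total = "clint_u_total_L_per_h",
  fm_cyp3a4 = "fm_cyp3a4_fraction",
  vss = "vss_L_per_kg", q_inter = "q_inter_L_per_h",
  vc_fraction = "vc_fraction", ka = "ka_per_h", fa = "fa_fraction",
  fg_baseline = "fg_baseline_fraction",
  clint_3a4_per_pmol = "clint_3a4_uL_per_min_per_pmol",
  hlm_nonCyp3a4 = "hlm_non_cyp3a4_uL_per_min_per_mg"
)

ind_key_map <- c(
  ind_max = "ind_max_fold_minus_1", ind_c50 = "ind_c50_ref_exposure",
  exposure_per_mg = "exposure_per_mg_daily",
  exposure_multiplier = "exposure_multiplier",
  kdeg_liver = "kdeg_liver_per_h", kdeg_gut = "kdeg_gut_per_h"
)

rename_fields <- function(x, map) stats::setNames(x[names(map)], unname(map))

#' Write / read parameter sets as structured text
#'
#' Serializes a [victim_pk()] and an [induction_spec()] (either may be
#' omitted) to YAML (`.yml`/`.yaml`) or JSON (`.json`), with units encoded
#' in the key names, and reads them back into the same objects.
#'
#' @param path File path; the extension selects the dialect.
#' @param pk Optional [victim_pk()].
#' @param ind Optional [induction_spec()].
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns `list(pk = , ind = )` with `NULL` for absent sections.
#' @export
write_config <- function(path, pk = NULL, ind = NULL) {
  out <- list()
  if (!is.null(pk)) {
    stopifnot(inherits(pk, "victim_pk"))
    out$victim_pk <- rename_fields(unclass(pk), pk_key_map)
  }
  if (!is.null(ind)) {
    stopifnot(inherits(ind, "induction_spec"))
    out$induction <- rename_fields(unclass(ind), ind_key_map)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    yaml::write_yaml(out, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  pk <- NULL
  if (!is.null(raw$victim_pk)) {
    v <- raw$victim_pk
    args <- lapply(stats::setNames(unname(pk_key_map), names(pk_key_map)),
                   function(k) as_num(v[[k]]))
    pk <- do.call(victim_pk, args)
  }
  ind <- NULL
  if (!is.null(raw$induction)) {
    v <- raw$induction
    args <- lapply(stats::setNames(unname(ind_key_map), names(ind_key_map)),
                   function(k) as_num(v[[k]]))
    ind <- do.call(induction_spec, args)
  }
  list(pk = pk, ind = ind)
}

#' Write a run manifest
#'
#' Records seed, configuration hash (of the serialized parameter objects),
#' package version and R version alongside any extra fields, as JSON.
#'
#' @param path Output path.
#' @param seed Integer seed used for the run.
#' @param pk,ind Parameter objects included in the hash.
#' @param extra Named list of additional fields.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, pk = NULL, ind = NULL, extra = list()) {
  payload <- jsonlite::toJSON(list(pk = unclass(pk), ind = unclass(ind)),
                              auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- c(list(
    seed = seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(as.character(payload)) *
                                        seq_along(utf8ToInt(as.character(payload)))) %% .Machine$integer.max),
    package = "lngpbpk",
    package_version = as.character(utils::packageVersion("lngpbpk")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
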