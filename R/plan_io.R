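PLAN_SCHEMA <- "needletrace-plan-1"

#' Write / read treatment plans as JSON
#'
#' The plan schema (`needletrace-plan-1`) is a plain JSON document:
#' `schema_version`, `prescription_dose_gy`, a `source` block
#' (`air_kerma_strength_U`, `dose_rate_constant`, `reference_r0_mm`,
#' `radial_dose` and `anisotropy` tables), and `needles`, a list of channels
#' each with `needle_id`, `step_mm`, `offset_mm`, `positions_mm` (list of
#' [x, y, z]) and `times_s`. Coordinates and times survive a round trip to
#' better than 1e-9.
#'
#' @param plan a [brachy_plan()].
#' @param path JSON file path.
#' @return `read_plan` returns a `brachy_plan`; `write_plan` returns `path`
#'   invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "brachy_plan"))
  src <- plan$source
  doc <- list(
    schema_version = PLAN_SCHEMA,
    prescription_dose_gy = plan$prescription_dose_gy,
    source = list(
      air_kerma_strength_U = src$air_kerma_strength,
      dose_rate_constant = src$dose_rate_constant,
      reference_r0_mm = src$reference_r0,
      radial_dose = list(r_mm = src$radial_dose$r_mm, g = src$radial_dose$g),
      anisotropy = list(r_mm = src$anisotropy$r_mm, phi = src$anisotropy$phi)),
    needles = lapply(plan$needles, function(n) list(
      needle_id = n$needle_id,
      step_mm = n$step_mm,
      offset_mm = n$offset_mm,
      positions_mm = unname(apply(n$positions, 1, as.numeric,
                                  simplify = FALSE)),
      times_s = as.numeric(n$times))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

require_fields <- function(x, fields, where) {
  missing <- fields[!fields %in% names(x)]
  if (length(missing))
    stop_cfg("read_plan: %s missing required field(s): %s", where,
             paste(missing, collapse = ", "))
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop_cfg("read_plan: no such file: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  require_fields(doc, c("schema_version", "prescription_dose_gy", "source",
                        "needles"), "plan")
  if (!identical(doc$schema_version, PLAN_SCHEMA))
    stop_cfg("read_plan: unsupported schema_version '%s' (expected '%s')",
             as.character(doc$schema_version), PLAN_SCHEMA)
  require_fields(doc$source, c("air_kerma_strength_U", "dose_rate_constant",
                               "reference_r0_mm", "radial_dose", "anisotropy"),
                 "source")
  src <- source_model(
    air_kerma_strength = doc$source$air_kerma_strength_U,
    dose_rate_constant = doc$source$dose_rate_constant,
    radial_dose = data.frame(
      r_mm = unlist(doc$source$radial_dose$r_mm),
      g = unlist(doc$source$radial_dose$g)),
    anisotropy = data.frame(
      r_mm = unlist(doc$source$anisotropy$r_mm),
      phi = unlist(doc$source$anisotropy$phi)),
    reference_r0 = doc$source$reference_r0_mm)
  needles <- lapply(seq_along(doc$needles), function(i) {
    nd <- doc$needles[[i]]
    require_fields(nd, c("needle_id", "step_mm", "offset_mm", "positions_mm",
                         "times_s"), sprintf("needles[%d]", i))
    pos <- do.call(rbind, lapply(nd$positions_mm, unlist))
    if (is.null(pos) || ncol(pos) != 3L)
      stop_cfg("read_plan: needles[%d] positions_mm must be [x,y,z] triples", i)
    colnames(pos) <- c("x", "y", "z")
    times <- unlist(nd$times_s)
    if (length(times) != nrow(pos))
      stop_cfg("read_plan: needles[%d] times_s length (%d) != positions (%d)",
               i, length(times), nrow(pos))
    structure(list(needle_id = nd$needle_id, positions = pos, times = times,
                   step_mm = nd$step_mm, offset_mm = nd$offset_mm),
              class = "dwell_set")
  })
  brachy_plan(needles, prescription_dose_gy = doc$prescription_dose_gy,
              source = src)
}
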