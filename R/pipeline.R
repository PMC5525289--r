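#' Quantify one cell: full trace-extraction pipeline
#'
#' Runs the complete region-quantification procedure on a time-lapse
#' stack: z-sum projection, optional rotation/crop from the annotation,
#' outside-cell background correction, cross-correlation drift correction,
#' keyframed region extraction, normalization of the pre-cytokinesis
#' reporter total to 1.0, and tracer-peak synchronization.
#'
#' @param stack A `timelapse_stack`.
#' @param annotation A `cell_annotation` (e.g. [default_annotation()] for
#'   simulated cells, or [read_annotation()] for annotated recordings).
#' @param reporter_channel,tracer_channel Channel names.
#' @param register_channel Channel used for drift registration (default:
#'   the silica tracer, whose entrapped mid-cell signal is the most
#'   stationary landmark; the reporter channel serves as fallback while
#'   the tracer is still dark).
#' @param upsample Sub-pixel registration factor (default 20 = 0.05 px).
#' @param drift_correct Apply drift correction (default `TRUE`).
#' @return A normalized, synchronized `trace_set`; the estimated
#'   `shift_trajectory` and background offsets are attached as attributes
#'   `shifts` and `background_offsets`.
#' @export
quantify_cell <- function(stack, annotation,
                          reporter_channel = "GFP",
                          tracer_channel = "PDMPO",
                          register_channel = tracer_channel,
                          upsample = 20L, drift_correct = TRUE) {
  stopifnot(inherits(stack, "timelapse_stack"),
            inherits(annotation, "cell_annotation"))
  proj <- z_project(stack)
  if (!is.null(annotation$rotation_deg) && annotation$rotation_deg != 0)
    proj <- rotate_projection(proj, annotation$rotation_deg)
  if (!is.null(annotation$crop))
    proj <- crop_projection(proj, annotation$crop)
  d <- dim(proj$data)
  regions <- keyframed_regions(annotation$regions, ny = d[3L], nx = d[4L],
                               n_frames = d[1L])
  bg <- background_correct(proj, annotation$outside_rect, regions)
  proj <- bg$projection
  shifts <- NULL
  if (drift_correct) {
    fb <- if (register_channel != reporter_channel) reporter_channel else NULL
    dc <- correct_drift(proj, channel = register_channel, upsample = upsample,
                        fallback_channel = fb)
    proj <- dc$projection
    shifts <- dc$shifts
  }
  traces <- extract_traces(proj, regions, cell_id = annotation$cell_id)
  traces <- normalize_traces(traces, annotation$cytokinesis_frame,
                             reporter_channel, tracer_channel)
  traces <- synchronize_traces(traces, tracer_channel)
  attr(traces, "shifts") <- shifts
  attr(traces, "background_offsets") <- bg$offsets
  traces
}
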