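#' Scene-parameter vocabulary
#'
#' The scene parameters an augmentation design may vary: background identity,
#' lighting conditions, foreground object pose, and 2-D camera viewpoint.
#' @export
SCENE_PARAMS <- c("background", "lighting", "object_pose", "camera_viewpoint")

#' Construct an augmentation design
#'
#' The design table maps every condition of a companion [response_matrix()]
#' to the latent structure that generated it.  Two modes exist:
#'
#' * **augmentation** mode: each condition is one augmented rendering of a
#'   base scene in which exactly one scene parameter (see [SCENE_PARAMS]) was
#'   varied; `base_scene_id`, `varied_param` and `level` are populated.  The
#'   canonical design is 100 base scenes x 4 parameters x 10 levels = 4000
#'   conditions.
#' * **grouped** mode: conditions carry only a `class_label` (e.g. object
#'   identity); nuisance variation is implicit.  This is the layout of
#'   neural recordings where identity and nuisance vary jointly.
#'
#' @param df data.frame with columns `condition_id` and, per mode,
#'   `base_scene_id`, `varied_param`, `level` (0-based integer) and/or
#'   `class_label`.  Empty strings / NA mark unused fields.
#' @return an object of class `augmentation_design` (a data.frame with a
#'   `mode` attribute).
#' @export
augmentation_design <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  assert_that("condition_id" %in% names(df),
              "design needs a condition_id column", "design_error")
  df$condition_id <- as.character(df$condition_id)
  assert_that(!anyDuplicated(df$condition_id),
              "duplicate condition_id in design", "design_error")
  for (col in c("base_scene_id", "varied_param", "level", "class_label")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  blank <- function(x) is.na(x) | x == ""
  has_aug <- !all(blank(df$base_scene_id)) || !all(blank(df$varied_param))
  has_cls <- !all(blank(df$class_label))
  if (has_aug) {
    assert_that(!any(blank(df$base_scene_id)) && !any(blank(df$varied_param)) &&
                  !any(is.na(df$level)),
                "augmentation mode requires base_scene_id, varied_param and level on every row",
                "design_error")
    df$base_scene_id <- as.character(df$base_scene_id)
    df$varied_param <- as.character(df$varied_param)
    bad <- setdiff(unique(df$varied_param), SCENE_PARAMS)
    if (length(bad) > 0)
      fg_stop(sprintf("unknown scene parameter(s): %s", paste(bad, collapse = ", ")),
              "vocabulary_error")
    df$level <- as.integer(df$level)
    assert_that(all(df$level >= 0L), "levels must be 0-based non-negative integers",
                "design_error")
    # within a base scene every varied parameter must offer the same number
    # of levels, and levels must not repeat within (scene, parameter)
    for (sc in unique(df$base_scene_id)) {
      sub <- df[df$base_scene_id == sc, ]
      counts <- table(sub$varied_param)
      if (length(unique(as.integer(counts))) > 1)
        fg_stop(sprintf("base scene '%s' has unequal level counts across parameters", sc),
                "design_error")
      if (anyDuplicated(paste(sub$varied_param, sub$level)))
        fg_stop(sprintf("base scene '%s' repeats a (parameter, level) pair", sc),
                "design_error")
    }
    mode <- "augmentation"
  } else if (has_cls) {
    df$class_label <- as.character(df$class_label)
    assert_that(!any(blank(df$class_label)),
                "grouped mode requires class_label on every row", "design_error")
    mode <- "grouped"
  } else {
    fg_stop("design populates neither augmentation nor class columns", "design_error")
  }
  attr(df, "mode") <- mode
  class(df) <- c("augmentation_design", "data.frame")
  df
}

#' Design mode
#' @param design an [augmentation_design()].
#' @return `"augmentation"` or `"grouped"`.
#' @export
design_mode <- function(design) attr(design, "mode")

#' Parameters available in a design
#'
#' Augmentation mode: the varied scene parameters.  Grouped mode: `"class"`
#' and `"non_class"` (between-class-center vs within-class structure).
#' @param design an [augmentation_design()].
#' @export
design_params <- function(design) {
  if (design_mode(design) == "augmentation") unique(design$varied_param)
  else c("class", "non_class")
}

#' Read / write an augmentation design
#'
#' CSV/TSV with header `condition_id, base_scene_id, varied_param, level,
#' class_label`; empty fields are allowed per mode.  The mode is inferred
#' from which columns are populated.
#' @param path file path.
#' @return a validated [augmentation_design()]; row order equals file order.
#' @export
read_design <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path), "io_error")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE, check.names = FALSE)
  augmentation_design(df)
}

#' @rdname read_design
#' @param design an [augmentation_design()].
#' @export
write_design <- function(design, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  cols <- c("condition_id", "base_scene_id", "varied_param", "level", "class_label")
  utils::write.table(as.data.frame(design)[, cols], path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# align a design with a response matrix; returns design rows in the response
# matrix's row order
align_design <- function(responses, design) {
  responses <- as_response_matrix(responses)
  idx <- match(condition_ids(responses), design$condition_id)
  assert_that(!any(is.na(idx)),
              "every condition in the response matrix must appear in the design",
              "alignment_error")
  out <- design[idx, , drop = FALSE]
  attr(out, "mode") <- design_mode(design)
  class(out) <- class(design)
  out
}
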