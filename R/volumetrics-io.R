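.norm_label <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' ROI alias table
#'
#' Mapping from common segmentation-tool column labels to the canonical
#' 18-ROI schema ([cerebellar_rois()]). The built-in table covers the
#' package's own names plus typical cerebellar-parcellation labels (e.g.
#' "Corpus Medullare" for cerebellar white matter, "Vermis VI-VII",
#' "Left Crus II"). Matching is case- and punctuation-insensitive. Extra
#' aliases can be supplied via a two-column CSV (`alias`, `canonical`); a
#' template ships at `system.file("extdata", "roi_aliases.csv", package =
#' "cerebmotor")`.
#'
#' @param alias_file Optional CSV of additional `alias,canonical` rows.
#' @return data.frame with columns `alias` (normalized) and `canonical`.
#' @export
roi_alias_table <- function(alias_file = NULL) {
  canon <- cerebellar_rois()
  base <- data.frame(alias = canon, canonical = canon,
                     stringsAsFactors = FALSE)
  extra <- list(
    c("corpus medullare", "white_matter"),
    c("cerebellar white matter", "white_matter"),
    c("cbm white matter", "white_matter"),
    c("vermis i v", "vermis_I_V"),
    c("vermal lobules i v", "vermis_I_V"),
    c("vermis vi vii", "vermis_VI_VII"),
    c("vermal lobules vi vii", "vermis_VI_VII"),
    c("vermis viii x", "vermis_VIII_X"),
    c("vermal lobules viii x", "vermis_VIII_X"))
  for (h in c("left", "right")) {
    extra <- c(extra, list(
      c(paste(h, "i v"), paste0(h, "_lobules_I_V")),
      c(paste(h, "lobules i v"), paste0(h, "_lobules_I_V")),
      c(paste(h, "vi"), paste0(h, "_lobule_VI")),
      c(paste(h, "lobule vi"), paste0(h, "_lobule_VI")),
      c(paste(h, "crus i"), paste0(h, "_crus_I")),
      c(paste(h, "crus ii"), paste0(h, "_crus_II_VIIB")),
      c(paste(h, "crus ii viib"), paste0(h, "_crus_II_VIIB")),
      c(paste(h, "crus ii lobule viib"), paste0(h, "_crus_II_VIIB")),
      c(paste(h, "viii"), paste0(h, "_lobule_VIII")),
      c(paste(h, "lobule viii"), paste0(h, "_lobule_VIII")),
      c(paste(h, "ix"), paste0(h, "_lobule_IX")),
      c(paste(h, "lobule ix"), paste0(h, "_lobule_IX")),
      c(paste(h, "x"), paste0(h, "_lobule_X")),
      c(paste(h, "lobule x"), paste0(h, "_lobule_X"))))
  }
  tab <- rbind(base, do.call(rbind, lapply(extra, function(e) {
    data.frame(alias = e[1], canonical = e[2], stringsAsFactors = FALSE)
  })))
  if (!is.null(alias_file)) {
    user <- utils::read.csv(alias_file, stringsAsFactors = FALSE)
    stopifnot(all(c("alias", "canonical") %in% names(user)))
    tab <- rbind(tab, user[, c("alias", "canonical")])
  }
  tab$alias <- .norm_label(tab$alias)
  bad <- !tab$canonical %in% canon
  if (any(bad)) {
    stop("alias targets must be canonical ROI names: ",
         paste(unique(tab$canonical[bad]), collapse = ", "))
  }
  tab[!duplicated(tab$alias), ]
}

.id_aliases <- c("participant_id", "participant", "subject", "subject_id",
                 "id", "sub")

#' Load and validate a cerebellar ROI volume table
#'
#' Reads a per-participant volume CSV such as produced by an automated
#' cerebellar segmentation tool, maps column labels onto the canonical 18-ROI
#' schema, converts units to cm^3, and validates the result: all 18 ROIs must
#' be present (a missing ROI is a named error), unknown columns are reported
#' via a warning (never silently dropped), and rows with non-positive
#' volumes are flagged in the `qc` attribute.
#'
#' @param path CSV path. One participant-id column plus ROI columns.
#' @param unit `"cm3"` (default) or `"mm3"` (divided by 1000 on load).
#' @param alias_file Optional extra alias CSV (see [roi_alias_table()]).
#' @return data.frame: `participant_id` plus the 18 canonical ROI columns, in
#'   cm^3, with attributes `qc` (data.frame of flagged rows) and
#'   `unknown_columns`.
#' @export
load_volume_table <- function(path, unit = c("cm3", "mm3"),
                              alias_file = NULL) {
  unit <- match.arg(unit)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  tab <- roi_alias_table(alias_file)
  norm <- .norm_label(names(raw))
  id_col <- which(norm %in% .id_aliases)[1]
  if (is.na(id_col)) stop("no participant-id column found in ", path)
  canon <- tab$canonical[match(norm, tab$alias)]
  unknown <- names(raw)[-id_col][is.na(canon[-id_col])]
  if (length(unknown)) {
    warning("unknown columns ignored: ", paste(unknown, collapse = ", "))
  }
  pretty <- function(roi) gsub("_", " ", sub("^(left|right)_", "\\1 ", roi))
  missing_rois <- setdiff(cerebellar_rois(), stats::na.omit(canon))
  if (length(missing_rois)) {
    stop("volume table is missing ROI column(s): ",
         paste(vapply(missing_rois, pretty, ""), collapse = ", "))
  }
  out <- data.frame(participant_id = as.character(raw[[id_col]]),
                    stringsAsFactors = FALSE)
  for (roi in cerebellar_rois()) {
    v <- as.numeric(raw[[which(canon == roi)[1]]])
    out[[roi]] <- if (unit == "mm3") v / 1000 else v
  }
  bad <- which(apply(out[cerebellar_rois()], 1,
                     function(r) any(!is.finite(r) | r <= 0)))
  qc <- out[bad, "participant_id", drop = FALSE]
  if (nrow(qc)) {
    warning("non-positive or missing volumes for participant(s): ",
            paste(qc$participant_id, collapse = ", "))
  }
  attr(out, "qc") <- qc
  attr(out, "unknown_columns") <- unknown
  out
}

#' Write a volume table to CSV
#'
#' @param table Volume table (canonical schema).
#' @param path Output CSV path.
#' @export
write_volume_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Derive composite volumes
#'
#' Adds `total_cerebellum`, the exact sum of the 18 ROI volumes. Volumes are
#' analyzed raw (no intracranial-volume normalization), so no other
#' composites are derived.
#'
#' @param table Volume table (canonical schema).
#' @return The table with a `total_cerebellum` column appended.
#' @export
derive_composites <- function(table) {
  missing_rois <- setdiff(cerebellar_rois(), names(table))
  if (length(missing_rois)) {
    stop("table is missing ROI column(s): ",
         paste(missing_rois, collapse = ", "))
  }
  table$total_cerebellum <- rowSums(table[, cerebellar_rois()])
  table
}
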