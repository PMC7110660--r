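#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom IRanges IRanges
NULL

.VALID_TIMEPOINTS <- c("T0", "Tfinal")
.VALID_ARMS <- c("no_radiation", "radiation")

#' Container for a pooled CRISPRi screen
#'
#' `ScreenExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with a single `"counts"` assay of non-negative integer sgRNA counts.
#' Rows are sgRNAs annotated (rowData) with `target_id`, `is_control` and
#' `protospacer`; columns are sequenced samples keyed (colData) by
#' `timepoint` (`"T0"`/`"Tfinal"`), `replicate` (positive integer) and
#' `arm` (`"no_radiation"`/`"radiation"`). The reserved non-targeting
#' label is kept in `metadata(x)$control_label`.
#'
#' @aliases ScreenExperiment-class
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    cnt <- assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "sgRNA ids (rownames) must be present and unique")
    rd <- rowData(object)
    need <- c("target_id", "is_control", "protospacer")
    if (!all(need %in% colnames(rd))) {
        msg <- c(msg, sprintf("rowData must contain: %s",
                              paste(need, collapse = ", ")))
    } else {
        lab <- metadata(object)$control_label
        if (is.null(lab))
            msg <- c(msg, "metadata(x)$control_label is required")
        else if (!identical(as.logical(rd$is_control),
                            rd$target_id == lab))
            msg <- c(msg,
                "is_control must be TRUE exactly for rows whose target_id is the control label")
    }
    cd <- colData(object)
    need <- c("timepoint", "replicate", "arm")
    if (!all(need %in% colnames(cd))) {
        msg <- c(msg, sprintf("colData must contain: %s",
                              paste(need, collapse = ", ")))
    } else {
        if (!all(cd$timepoint %in% .VALID_TIMEPOINTS))
            msg <- c(msg, sprintf("timepoint labels must be in {%s}",
                                  paste(.VALID_TIMEPOINTS, collapse = ", ")))
        if (!all(cd$arm %in% .VALID_ARMS))
            msg <- c(msg, sprintf("arm labels must be in {%s}",
                                  paste(.VALID_ARMS, collapse = ", ")))
        if (any(cd$replicate != floor(cd$replicate)) || any(cd$replicate < 1))
            msg <- c(msg, "replicate must be a positive integer")
        key <- paste(cd$timepoint, cd$replicate, cd$arm)
        if (anyDuplicated(key))
            msg <- c(msg, "each (timepoint, replicate, arm) combination may occur only once")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ScreenExperiment
#'
#' @param counts integer matrix of sgRNA counts with sgRNA ids as rownames
#'   and one column per sequenced sample.
#' @param guides guide table as returned by [readGuideTable()]: a
#'   data.frame with columns `sgrna_id`, `target_id`, `protospacer`,
#'   `is_control`.
#' @param samples data.frame with one row per column of `counts` and
#'   columns `timepoint`, `replicate`, `arm`.
#' @param control_label reserved target label of non-targeting control
#'   sgRNAs.
#'
#' @details sgRNAs present in `counts` but absent from `guides` are a hard
#'   error: silently dropping misannotated guides would corrupt the
#'   control statistics.
#'
#' @return A [ScreenExperiment-class] object.
#' @examples
#' gt <- data.frame(sgrna_id = c("sg1", "sg2"),
#'                  target_id = c("geneA", "negative_control"),
#'                  protospacer = "", is_control = c(FALSE, TRUE))
#' cnt <- matrix(1:4, 2, dimnames = list(c("sg1", "sg2"), c("a", "b")))
#' ss <- data.frame(timepoint = c("T0", "Tfinal"), replicate = 1L,
#'                  arm = "radiation")
#' ScreenExperiment(cnt, gt, ss)
#' @export
ScreenExperiment <- function(counts, guides, samples,
                             control_label = "negative_control") {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("counts must have sgRNA ids as rownames")
    unknown <- setdiff(rownames(counts), guides$sgrna_id)
    if (length(unknown))
        stop("sgRNAs present in counts but absent from the guide table: ",
             paste(utils::head(unknown, 5), collapse = ", "),
             if (length(unknown) > 5) sprintf(" (and %d more)", length(unknown) - 5))
    gi <- guides[match(rownames(counts), guides$sgrna_id), , drop = FALSE]
    rd <- DataFrame(target_id = gi$target_id,
                    is_control = gi$target_id == control_label,
                    protospacer = gi$protospacer,
                    row.names = rownames(counts))
    cd <- DataFrame(timepoint = as.character(samples$timepoint),
                    replicate = as.integer(samples$replicate),
                    arm = as.character(samples$arm),
                    row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowData = rd, colData = cd)
    metadata(se)$control_label <- control_label
    new("ScreenExperiment", se)
}

#' Accessors for ScreenExperiment
#'
#' `guideTargets()` returns the target id of each sgRNA, `isControl()` the
#' non-targeting flag, and `controlLabel()` the reserved control label.
#'
#' @param x a [ScreenExperiment-class].
#' @return `guideTargets()` and `controlLabel()` return character vectors;
#'   `isControl()` a logical vector.
#' @rdname ScreenExperiment-accessors
#' @export
setGeneric("guideTargets", function(x) standardGeneric("guideTargets"))

#' @rdname ScreenExperiment-accessors
#' @export
setMethod("guideTargets", "ScreenExperiment",
          function(x) rowData(x)$target_id)

#' @rdname ScreenExperiment-accessors
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @rdname ScreenExperiment-accessors
#' @export
setMethod("isControl", "ScreenExperiment",
          function(x) as.logical(rowData(x)$is_control))

#' @rdname ScreenExperiment-accessors
#' @export
setGeneric("controlLabel", function(x) standardGeneric("controlLabel"))

#' @rdname ScreenExperiment-accessors
#' @export
setMethod("controlLabel", "ScreenExperiment",
          function(x) metadata(x)$control_label)

setMethod("show", "ScreenExperiment", function(object) {
    cd <- colData(object)
    cat(sprintf("ScreenExperiment: %d sgRNAs x %d samples\n",
                nrow(object), ncol(object)))
    cat(sprintf("  targets: %d (+ %d non-targeting controls, label '%s')\n",
                length(unique(guideTargets(object)[!isControl(object)])),
                sum(isControl(object)), controlLabel(object)))
    cat(sprintf("  arms: %s | replicates: %s | timepoints: %s\n",
                paste(unique(cd$arm), collapse = ", "),
                paste(sort(unique(cd$replicate)), collapse = ", "),
                paste(unique(cd$timepoint), collapse = ", ")))
})
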