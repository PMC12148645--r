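#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SAFExperiment: bundle-feature values for a cohort
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"features"` (rows = pathway x tier x feature, columns =
#' participants) with cohort covariates (Age in years, Sex coded 0 =
#' female / 1 = male, TICV) in `colData` and the bundle annotation
#' (pathway, tier, feature) in `rowData`.
#'
#' @export
setClass("SAFExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    rd <- rowData(object)
    if (!all(c("pathway", "tier", "feature") %in% colnames(rd)))
      msg <- c(msg, "rowData must contain pathway, tier, feature")
    else if (!all(rd$tier %in% TIERS))
      msg <- c(msg, "tier must be SAF or LR")
    cd <- colData(object)
    if (!all(c("Age", "Sex", "TICV") %in% colnames(cd)))
      msg <- c(msg, "colData must contain Age, Sex, TICV")
    else if (!all(cd$Sex %in% c(0, 1)))
      msg <- c(msg, "Sex must be coded 0 (female) / 1 (male)")
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'features' is required")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an SAFExperiment
#'
#' @param values numeric matrix, rows = bundle-feature combinations,
#'   columns = participants.
#' @param rowData data.frame/DataFrame with pathway, tier, feature per row.
#' @param colData data.frame/DataFrame with Age, Sex, TICV per participant.
#' @param metadata optional list (e.g. the generating [SimDesign-class]).
#' @return An [SAFExperiment-class].
#' @export
SAFExperiment <- function(values, rowData, colData, metadata = list()) {
  se <- SummarizedExperiment(assays = list(features = as.matrix(values)),
    rowData = DataFrame(rowData), colData = DataFrame(colData),
    metadata = metadata)
  new("SAFExperiment", se)
}

#' Cohort covariate table of an SAFExperiment
#'
#' @param se an [SAFExperiment-class]
#' @return data.frame with participant_id, Age, Sex, TICV.
#' @export
cohortTable <- function(se) {
  cd <- colData(se)
  data.frame(participant_id = colnames(se), Age = cd$Age, Sex = cd$Sex,
             TICV = cd$TICV, row.names = NULL)
}

#' Long-format bundle-feature table
#'
#' @param se an [SAFExperiment-class]
#' @return data.frame with participant_id, pathway, tier, feature, value.
#' @export
featureTable <- function(se) {
  rd <- as.data.frame(rowData(se))
  m <- assay(se, "features")
  data.frame(
    participant_id = rep(colnames(se), each = nrow(m)),
    pathway = rep(rd$pathway, ncol(m)),
    tier = rep(rd$tier, ncol(m)),
    feature = rep(rd$feature, ncol(m)),
    value = as.vector(m), row.names = NULL)
}

#' Pathway labels present in an SAFExperiment
#' @param se an [SAFExperiment-class]
#' @export
pathwayLabels <- function(se) unique(as.character(rowData(se)$pathway))

## Row index for a (pathway, tier, feature) triple.
bundleRow <- function(se, pathway, tier, feature) {
  rd <- rowData(se)
  which(rd$pathway == pathway & rd$tier == tier & rd$feature == feature)
}

#' Extract one bundle-feature vector across participants
#' @param se an [SAFExperiment-class]
#' @param pathway,tier,feature bundle coordinates.
#' @return numeric vector, one value per participant.
#' @export
bundleValues <- function(se, pathway, tier, feature) {
  i <- bundleRow(se, pathway, tier, feature)
  if (length(i) != 1L)
    stop("no unique row for ", pathway, "/", tier, "/", feature)
  assay(se, "features")[i, ]
}
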