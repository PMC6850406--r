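#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the signal and spectrum classes:
#' \code{samples()} returns the raw sample vector, \code{samplingRate()} the
#' sampling rate in Hz, \code{nTrials()} the number of equal-length trials
#' concatenated in the object, \code{conditionLabel()}, \code{subjectId()} and
#' \code{roiLabel()} the metadata labels.
#'
#' @param x an object of one of the speechPAC S4 classes
#' @return the corresponding slot value
#' @name accessors
#' @aliases samples samplingRate nTrials conditionLabel subjectId roiLabel
#' @export samples samplingRate nTrials conditionLabel subjectId roiLabel
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname accessors
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' Spectrum accessors
#'
#' \code{spectrumFreqs()} returns the frequency grid of a
#' \linkS4class{CoherenceSpectrum}; \code{coherenceValues()} the coherence
#' values on that grid; \code{nSegments()} the number of Welch segments that
#' entered the estimate.
#'
#' @param x a \linkS4class{CoherenceSpectrum}
#' @return numeric vector (or integer for \code{nSegments})
#' @name spectrum-accessors
#' @aliases spectrumFreqs coherenceValues nSegments
#' @export spectrumFreqs coherenceValues nSegments
setGeneric("spectrumFreqs", function(x) standardGeneric("spectrumFreqs"))

#' @rdname spectrum-accessors
setGeneric("coherenceValues", function(x) standardGeneric("coherenceValues"))

#' @rdname spectrum-accessors
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Comodulogram accessors
#'
#' \code{miMatrix()} returns the mutual-information matrix (bits) with phase
#' frequencies in rows and amplitude frequencies in columns;
#' \code{phaseFreqs()} and \code{ampFreqs()} the two frequency grids;
#' \code{phaseSource()} whether phase was taken from the stimulus envelope or
#' from the neural signal.
#'
#' @param x a \linkS4class{Comodulogram}
#' @return matrix, numeric vector or character scalar
#' @name comodulogram-accessors
#' @aliases miMatrix phaseFreqs ampFreqs phaseSource
#' @export miMatrix phaseFreqs ampFreqs phaseSource
setGeneric("miMatrix", function(x) standardGeneric("miMatrix"))

#' @rdname comodulogram-accessors
setGeneric("phaseFreqs", function(x) standardGeneric("phaseFreqs"))

#' @rdname comodulogram-accessors
setGeneric("ampFreqs", function(x) standardGeneric("ampFreqs"))

#' @rdname comodulogram-accessors
setGeneric("phaseSource", function(x) standardGeneric("phaseSource"))

#' Cohort accessors
#'
#' \code{cohortConfigOf()} returns the \linkS4class{CohortConfig} a cohort was
#' generated from; \code{groundTruth()} the per-subject ground-truth table
#' (subject id, syllable rate, gamma frequency); \code{cohortEnvelope()} and
#' \code{cohortNeural()} retrieve one subject/condition stimulus envelope or
#' one subject/condition/ROI neural trace.
#'
#' @param x a \linkS4class{SyntheticCohort}
#' @param subject subject id, e.g. \code{"s01"}
#' @param condition condition label, e.g. \code{"normal"}
#' @param roi ROI label, e.g. \code{"LAC"}
#' @return see each accessor's description
#' @name cohort-accessors
#' @aliases cohortConfigOf groundTruth cohortEnvelope cohortNeural
#' @export cohortConfigOf groundTruth cohortEnvelope cohortNeural
setGeneric("cohortConfigOf", function(x) standardGeneric("cohortConfigOf"))

#' @rdname cohort-accessors
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname cohort-accessors
setGeneric("cohortEnvelope", function(x, subject, condition)
  standardGeneric("cohortEnvelope"))

#' @rdname cohort-accessors
setGeneric("cohortNeural", function(x, subject, condition, roi)
  standardGeneric("cohortNeural"))
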