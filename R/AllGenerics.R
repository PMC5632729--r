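## Generics and simple accessors for the package's S4 classes.

#' @rdname AnnotatedPlastome-class
#' @param object,x an object.
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))

#' @rdname AnnotatedPlastome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname AnnotatedPlastome-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname AnnotatedPlastome-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname AnnotatedPlastome-class
#' @export
setGeneric("features<-", function(x, value) standardGeneric("features<-"))

#' @rdname AnnotatedPlastome-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @export
#' @rdname AnnotatedPlastome-class
setMethod("identifier", "AnnotatedPlastome", function(x) x@identifier)

#' @export
#' @rdname AnnotatedPlastome-class
setMethod("genomeSeq", "AnnotatedPlastome", function(x) x@sequence)

#' @export
#' @rdname AnnotatedPlastome-class
setMethod("genomeLength", "AnnotatedPlastome",
          function(x) length(x@sequence))

#' @export
#' @rdname AnnotatedPlastome-class
setMethod("features", "AnnotatedPlastome", function(x) x@features)

#' @export
#' @rdname AnnotatedPlastome-class
setMethod("features<-", "AnnotatedPlastome", function(x, value) {
  x@features <- value
  validObject(x)
  x
})

#' @export
#' @rdname AnnotatedPlastome-class
setMethod("isCircular", "AnnotatedPlastome", function(x) x@circular)

## RegionPartition accessors ----------------------------------------------

#' @rdname RegionPartition-class
#' @param x a RegionPartition.
#' @export
setGeneric("lscRegion", function(x) standardGeneric("lscRegion"))
#' @rdname RegionPartition-class
#' @export
setGeneric("sscRegion", function(x) standardGeneric("sscRegion"))
#' @rdname RegionPartition-class
#' @export
setGeneric("irbRegion", function(x) standardGeneric("irbRegion"))
#' @rdname RegionPartition-class
#' @export
setGeneric("iraRegion", function(x) standardGeneric("iraRegion"))
#' @rdname RegionPartition-class
#' @export
setGeneric("irLength", function(x) standardGeneric("irLength"))
#' @rdname RegionPartition-class
#' @export
setGeneric("lscLength", function(x) standardGeneric("lscLength"))
#' @rdname RegionPartition-class
#' @export
setGeneric("sscLength", function(x) standardGeneric("sscLength"))
#' @rdname RegionPartition-class
#' @export
setGeneric("jsa", function(x) standardGeneric("jsa"))
#' @rdname RegionPartition-class
#' @export
setGeneric("jsb", function(x) standardGeneric("jsb"))

#' @export
#' @rdname RegionPartition-class
setMethod("lscRegion", "RegionPartition", function(x) x@lsc)
#' @export
#' @rdname RegionPartition-class
setMethod("sscRegion", "RegionPartition", function(x) x@ssc)
#' @export
#' @rdname RegionPartition-class
setMethod("irbRegion", "RegionPartition", function(x) x@irb)
#' @export
#' @rdname RegionPartition-class
setMethod("iraRegion", "RegionPartition", function(x) x@ira)
#' @export
#' @rdname RegionPartition-class
setMethod("irLength", "RegionPartition", function(x) width(x@irb))
#' @export
#' @rdname RegionPartition-class
setMethod("lscLength", "RegionPartition", function(x) width(x@lsc))
#' @export
#' @rdname RegionPartition-class
setMethod("sscLength", "RegionPartition", function(x) width(x@ssc))
#' @export
#' @rdname RegionPartition-class
setMethod("jsa", "RegionPartition", function(x) end(x@ssc))
#' @export
#' @rdname RegionPartition-class
setMethod("jsb", "RegionPartition", function(x) start(x@ssc))

## JunctionProfile accessors ----------------------------------------------

#' @rdname JunctionProfile-class
#' @param x a JunctionProfile.
#' @export
setGeneric("ndhStatus", function(x) standardGeneric("ndhStatus"))
#' @rdname JunctionProfile-class
#' @export
setGeneric("typeLabel", function(x) standardGeneric("typeLabel"))
#' @rdname JunctionProfile-class
#' @export
setGeneric("ycf1ToJsa", function(x) standardGeneric("ycf1ToJsa"))
#' @rdname JunctionProfile-class
#' @export
setGeneric("retainedNdhLength", function(x) standardGeneric("retainedNdhLength"))

#' @export
#' @rdname JunctionProfile-class
setMethod("ndhStatus", "JunctionProfile", function(x) x@ndhStatus)
#' @export
#' @rdname JunctionProfile-class
setMethod("typeLabel", "JunctionProfile", function(x) x@typeLabel)
#' @export
#' @rdname JunctionProfile-class
setMethod("ycf1ToJsa", "JunctionProfile", function(x) x@ycf1ToJsa)
#' @export
#' @rdname JunctionProfile-class
setMethod("retainedNdhLength", "JunctionProfile",
          function(x) x@retainedNdhLength)
#' @export
#' @rdname JunctionProfile-class
setMethod("identifier", "JunctionProfile", function(x) x@identifier)

## SimTruth accessors ------------------------------------------------------

#' @rdname SimTruth-class
#' @param x a SimTruth.
#' @export
setGeneric("truePartition", function(x) standardGeneric("truePartition"))
#' @rdname SimTruth-class
#' @export
setGeneric("plantedSSRs", function(x) standardGeneric("plantedSSRs"))
#' @rdname SimTruth-class
#' @export
setGeneric("plantedRepeats", function(x) standardGeneric("plantedRepeats"))
#' @rdname SimTruth-class
#' @export
setGeneric("plantedLoci", function(x) standardGeneric("plantedLoci"))
#' @rdname SimTruth-class
#' @export
setGeneric("mutationLedger", function(x) standardGeneric("mutationLedger"))
#' @rdname SimTruth-class
#' @export
setGeneric("scenarioLabel", function(x) standardGeneric("scenarioLabel"))

#' @export
#' @rdname SimTruth-class
setMethod("truePartition", "SimTruth", function(x) x@partition)
#' @export
#' @rdname SimTruth-class
setMethod("plantedSSRs", "SimTruth", function(x) x@ssrs)
#' @export
#' @rdname SimTruth-class
setMethod("plantedRepeats", "SimTruth", function(x) x@repeats)
#' @export
#' @rdname SimTruth-class
setMethod("plantedLoci", "SimTruth", function(x) x@loci)
#' @export
#' @rdname SimTruth-class
setMethod("mutationLedger", "SimTruth", function(x) x@mutations)
#' @export
#' @rdname SimTruth-class
setMethod("scenarioLabel", "SimTruth", function(x) x@scenario)
#' @export
#' @rdname SimTruth-class
setMethod("retainedNdhLength", "SimTruth", function(x) x@retainedNdhLength)
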