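#' @include AllClasses.R
NULL

#' Accessors for ProteinDatabase and HCPProfile objects
#'
#' `accession`, `category` and `description` extract per-entry annotation
#' from a [ProteinDatabase-class]; `sequences` returns the underlying
#' `AAStringSet`. `members`, `profileLevel` and `profileKey` extract the
#' contents of an [HCPProfile-class].
#'
#' @param x A `ProteinDatabase` or `HCPProfile`.
#' @return The corresponding slot contents.
#' @examples
#' db <- ProteinDatabase("P1", "MKAAAR")
#' accession(db)
#' category(db)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname accessors
#' @export
setGeneric("category", function(x) standardGeneric("category"))
#' @rdname accessors
#' @export
setGeneric("description", function(x) standardGeneric("description"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("profileLevel", function(x) standardGeneric("profileLevel"))
#' @rdname accessors
#' @export
setGeneric("profileKey", function(x) standardGeneric("profileKey"))

#' @rdname accessors
#' @export
setMethod("accession", "ProteinDatabase", function(x) names(x@sequences))
#' @rdname accessors
#' @export
setMethod("category", "ProteinDatabase", function(x)
  setNames(x@category, names(x@sequences)))
#' @rdname accessors
#' @export
setMethod("description", "ProteinDatabase", function(x)
  setNames(x@description, names(x@sequences)))
#' @rdname accessors
#' @export
setMethod("sequences", "ProteinDatabase", function(x) x@sequences)

#' @describeIn accessors Number of database entries.
#' @export
setMethod("length", "ProteinDatabase", function(x) length(x@sequences))

#' Subset a protein database
#'
#' @param x A [ProteinDatabase-class].
#' @param i Index, logical mask or accession vector.
#' @param j,drop,... Ignored.
#' @return A `ProteinDatabase` with the selected entries.
#' @export
setMethod("[", "ProteinDatabase", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("ProteinDatabase", sequences = x@sequences[i],
      category = x@category[i], description = x@description[i])
})

setMethod("show", "ProteinDatabase", function(object) {
  cat(sprintf("ProteinDatabase with %d entries\n", length(object)))
  if (length(object)) {
    tab <- table(object@category)
    cat("  categories:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

#' Coerce a protein database to a data.frame
#'
#' @param x A [ProteinDatabase-class].
#' @param row.names,optional,... Passed for generic compatibility; unused.
#' @return data.frame with columns accession, sequence, category,
#'   description.
#' @export
as.data.frame.ProteinDatabase <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(accession = names(x@sequences),
             sequence = as.character(x@sequences),
             category = x@category, description = x@description,
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("members", "HCPProfile", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("profileLevel", "HCPProfile", function(x) x@level)
#' @rdname accessors
#' @export
setMethod("profileKey", "HCPProfile", function(x) x@key)

#' @describeIn accessors Number of profile members.
#' @export
setMethod("length", "HCPProfile", function(x) length(x@members))

setMethod("show", "HCPProfile", function(object) {
  cat(sprintf("HCPProfile [%s] %s: %d member(s)\n", object@level,
              paste(object@key, collapse = "/"), length(object@members)))
  if (length(object@members)) {
    tab <- table(factor(object@members, levels = 1:4))
    cat("  tiers 1..4:", paste(tab, collapse = "/"), "\n")
  }
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %s: %s\n", s, paste(slot(object, s), collapse = ", ")))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (is.list(v)) v <- sprintf("<list of %d>", length(v))
    cat(sprintf("  %s: %s\n", s, paste(v, collapse = ", ")))
  }
})
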