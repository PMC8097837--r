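#' Gene identifiers of an object
#'
#' @param x a \linkS4class{GeneCatalog}, \linkS4class{GeneAbundance} or
#'   \linkS4class{CAGPartition}.
#' @return Character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Specimen identifiers of an object
#'
#' @param x a \linkS4class{GeneAbundance}.
#' @return Character vector of specimen identifiers.
#' @export
setGeneric("specimens", function(x) standardGeneric("specimens"))

#' Gene lengths in amino acids
#'
#' @param x a \linkS4class{GeneCatalog}.
#' @return Named integer vector of amino-acid lengths.
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' Length-normalized sequencing depth matrix
#'
#' @param x a \linkS4class{GeneAbundance}.
#' @return Numeric gene-by-specimen matrix of sequencing depth (aligned
#'   nucleotides divided by nucleotide gene length).
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))

#' Relative abundance matrix
#'
#' @param x a \linkS4class{GeneAbundance}.
#' @return Numeric gene-by-specimen matrix; each specimen column sums to 1
#'   over detected genes.
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' CAG identifiers of a partition
#'
#' @param x a \linkS4class{CAGPartition}.
#' @return Character vector of CAG identifiers.
#' @export
setGeneric("cagIds", function(x) standardGeneric("cagIds"))

#' Member genes of one CAG
#'
#' @param x a \linkS4class{CAGPartition}.
#' @param cag a single CAG identifier.
#' @return Character vector of member gene identifiers.
#' @export
setGeneric("members", function(x, cag) standardGeneric("members"))

#' Gene-to-CAG membership map
#'
#' @param x a \linkS4class{CAGPartition}.
#' @return Named character vector mapping gene_id to cag_id.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' Number of CAGs in a partition
#'
#' @param x a \linkS4class{CAGPartition}.
#' @return Integer scalar.
#' @export
setGeneric("nCags", function(x) standardGeneric("nCags"))
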