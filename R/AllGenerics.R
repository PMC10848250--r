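#' Number of atoms
#' @param x a Molecule or ConformerEnsemble.
#' @return integer atom count A.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of conformer frames
#' @param x a ConformerEnsemble.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Element symbols of the atoms
#' @param x a Molecule, ConformerEnsemble or DescriptorResult.
#' @return character vector of element symbols.
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' Cartesian coordinates
#' @param x a Molecule.
#' @return numeric A x 3 matrix (Angstrom).
#' @export
setGeneric("atomCoordinates", function(x) standardGeneric("atomCoordinates"))

#' Bond index pairs
#' @param x a Molecule or ConformerEnsemble.
#' @return integer two-column matrix of 1-based bonded atom pairs.
#' @export
setGeneric("molBonds", function(x) standardGeneric("molBonds"))

#' Identifier of a molecule, ensemble or descriptor result
#' @param x the object.
#' @return character scalar.
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))

#' R-GETAWAY autocorrelation descriptor
#'
#' @param x a Molecule (returns a [DescriptorResult-class]) or a
#'   ConformerEnsemble (returns one numeric value per frame).
#' @param k positive integer topological lag (3 for R3m).
#' @param weights "mass" for atomic masses normalized to carbon, or "unit".
#' @return See the method descriptions.
#' @export
setGeneric("rAutocorrelation",
           function(x, k = 3L, weights = c("mass", "unit"))
               standardGeneric("rAutocorrelation"))

#' R3m: third-order mass-weighted R-GETAWAY autocorrelation
#' @param x a Molecule or ConformerEnsemble.
#' @return [DescriptorResult-class] for a Molecule; numeric vector for an
#'   ensemble.
#' @export
setGeneric("r3m", function(x) standardGeneric("r3m"))

#' Descriptor value
#' @param x a DescriptorResult.
#' @return numeric scalar.
#' @export
setGeneric("descriptorValue", function(x) standardGeneric("descriptorValue"))

#' Per-atom descriptor contributions
#' @param x a DescriptorResult.
#' @return numeric length-A vector summing to the descriptor value.
#' @export
setGeneric("perAtomContributions",
           function(x) standardGeneric("perAtomContributions"))

#' Leverages (diagonal of the molecular influence matrix)
#' @param x an InfluenceResult or DescriptorResult.
#' @return numeric vector of h_ii values.
#' @export
setGeneric("leverages", function(x) standardGeneric("leverages"))

#' Extract one conformer as a Molecule
#' @param x a ConformerEnsemble.
#' @param i frame index.
#' @return a [Molecule-class].
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' 50% decision boundary of a logistic dispersibility model
#'
#' The R3m value at which the model predicts probability one half,
#' \code{-intercept/slope}.
#' @param model a [LogisticModel-class].
#' @return numeric scalar.
#' @export
setGeneric("decisionBoundary",
           function(model) standardGeneric("decisionBoundary"))
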