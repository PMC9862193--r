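# Registries for species, reactions and kinetic constants. The canonical
# ordering lives in the compiled code (cpp_model_info()); the copies here are
# the human-readable contract and are checked against the compiled registry by
# the test suite.

#' Biomass volume fraction (L cytosol per g dry weight)
#'
#' Conversion between cytosolic-volume and biomass bases for rates expressed
#' in mM s^-1 of intracellular volume.
#' @export
BIOMASS_VOLUME_FRACTION <- 0.002

#' Molar mass of glucose (g/mol), used for g/L <-> mM conversions
#' @export
GLUCOSE_MW <- 180.156

.registry <- new.env(parent = emptyenv())

.model_info <- function() {
  if (is.null(.registry$info)) .registry$info <- cpp_model_info()
  .registry$info
}

#' Model species names
#'
#' All state variables in canonical order: cytosolic metabolites and cofactors
#' (mM, cytosolic volume), vacuolar trehalose `TREv` (mM, vacuolar volume),
#' extracellular glucose/trehalose (mM, broth volume) and the broth volume
#' `VOL` (L).
#' @return character vector
#' @export
model_species <- function() as.character(.model_info()$species)

#' Model reaction identifiers in canonical flux-vector order
#' @return character vector
#' @export
model_reactions <- function() as.character(.model_info()$reactions)

#' Names of all kinetic constants ("REACTION.constant")
#' @return character vector
#' @export
model_parameters <- function() as.character(.model_info()$parameters)

#' Carbon-tracked species (those with a 13C-labelled counterpart)
#' @return character vector
#' @export
carbon_species <- function() {
  info <- .model_info()
  as.character(info$species[info$carbon_idx])
}

#' Reversibility flags per reaction
#' @return named logical vector
#' @export
reaction_reversible <- function() {
  info <- .model_info()
  setNames(as.logical(info$reversible), as.character(info$reactions))
}

#' Stoichiometric matrix of the cytosolic network
#'
#' Rows are species, columns reactions, entries in cytosolic-volume units.
#' Cross-compartment handling (vacuole volume ratio, broth-volume dilution of
#' extracellular species) is applied by the right-hand-side assembly, not by
#' this matrix; the extracellular/vacuolar rows hold the cytosolic-basis
#' transfer stoichiometry. Moiety conservation (ATP+ADP+AMP, NAD+NADH) is a
#' left-null-space property of this matrix.
#' @return numeric matrix with dimnames (species x reactions)
#' @export
stoichiometry_matrix <- function() {
  sp <- model_species()
  rx <- model_reactions()
  S <- matrix(0, length(sp), length(rx), dimnames = list(sp, rx))
  put <- function(rxn, ...) {
    entries <- c(...)
    S[names(entries), rxn] <<- entries
  }
  put("HXT", c(GLCec = -1, GLCi = 1))
  put("HXK", c(GLCi = -1, ATP = -1, G6P = 1, ADP = 1))
  put("PGI", c(G6P = -1, F6P = 1))
  put("PFK", c(F6P = -1, ATP = -1, FBP = 1, ADP = 1))
  put("FBA", c(FBP = -1, DHAP = 1, GAP = 1))
  put("TPI", c(DHAP = -1, GAP = 1))
  put("GAPDH", c(GAP = -1, NAD = -1, PI = -1, BPG = 1, NADH = 1))
  put("PGK", c(BPG = -1, ADP = -1, P3G = 1, ATP = 1))
  put("GPM", c(P3G = -1, P2G = 1))
  put("ENO", c(P2G = -1, PEP = 1))
  put("PYK", c(PEP = -1, ADP = -1, PYR = 1, ATP = 1))
  put("PDC", c(PYR = -1, ACE = 1))
  put("ADH", c(ACE = -1, NADH = -1, NAD = 1))          # ethanol leaves the system
  put("G3PDH", c(DHAP = -1, NADH = -1, G3P = 1, NAD = 1))
  put("GPP", c(G3P = -1, GLYCEROL = 1, PI = 1))
  put("GLYC_EX", c(GLYCEROL = -1))                     # excreted, not tracked
  put("PGM1", c(G6P = -1, G1P = 1))
  put("UGP", c(G1P = -1, ATP = -1, UDPG = 1, ADP = 1)) # UTP/UDP proxied by ATP/ADP
  put("TPS1", c(G6P = -1, UDPG = -1, T6P = 1))         # UDP release not adenylate-tracked
  put("TPS2", c(T6P = -1, TREc = 1, PI = 1))
  put("NTH1", c(TREc = -1, GLCi = 2))
  put("AGT1", c(TREc = -1, TREec = 1))
  put("VACT", c(TREc = -1, TREv = 1))
  put("ATH1", c(TREv = -1, GLCi = 2))
  put("GLY_SYNTH", c(UDPG = -1, GLYCOGEN = 1))
  put("GLY_DEG", c(GLYCOGEN = -1, G1P = 1, PI = -1))
  put("ATPase", c(ATP = -1, ADP = 1, PI = 1))
  put("ADK", c(ATP = -1, AMP = -1, ADP = 2))
  put("MITO_NADH", c(NADH = -1, ADP = -1, PI = -1, NAD = 1, ATP = 1))
  put("PIBUF", c(PI = 1))                              # polyphosphate exchange
  put("sink_G6P", c(G6P = -1))
  put("sink_P3G", c(P3G = -1))
  put("sink_PYR", c(PYR = -1))
  put("sink_ACE", c(ACE = -1))
  S
}

#' Convert glucose concentration between g/L and mM
#' @param x numeric values
#' @return converted values
#' @rdname glucose-units
#' @export
glc_gL_to_mM <- function(x) x * 1000 / GLUCOSE_MW

#' @rdname glucose-units
#' @export
glc_mM_to_gL <- function(x) x * GLUCOSE_MW / 1000
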