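# Builds the shipped reference model files under inst/extdata/:
#   cho_network.yaml, cho_parameters.csv,
#   experiment_{biogro,powercho}_{batch,fedbatch}.yaml,
#   toy_network.yaml, toy_parameters.csv, toy_experiment.yaml,
#   reference_sensitivity.csv
#
# The network is a reconstruction: the reaction set, regulation wiring,
# conversion factors and printed concentrations come from the published
# description of this model family; rate-law algebraic details and parameter
# values not printed in the main text are chosen so that nominal fluxes sit in
# the reported ranges (V_HK ~ 2e-4, V_PDH ~ 1.6e-5, V_G6PDH ~ 3.5e-6
# mmol/1e6 cells/h at mid-exponential phase). Maximal rates are derived from
# those target nominal fluxes by evaluating each rate law's saturation and
# regulation terms at the nominal reference state and solving for Vmax.
#
# Run from the package root:  Rscript data-raw/make_reference_model.R

pkgload::load_all(".", quiet = TRUE)

out_dir <- "inst/extdata"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

aa <- c("ALA", "ARG", "ASP", "ASN", "GLN", "GLU", "GLY", "HIS", "ILE",
        "LYS", "MET", "PHE", "SER", "THR", "TYR", "VAL")

# ---- nominal reference state (mid-exponential) -------------------------------
nominal <- c(
  Xv = 1.0, V = 1.0, mAb = 10,
  GLC = 18, GLN = 3, GLU = 0.5, LAC = 5, NH4 = 1.5,
  ALA = 0.5, ASP = 0.4, ASN = 1.2, SER = 0.9, GLY = 0.7, HIS = 0.5,
  ARG = 1.4, ILE = 1.6, VAL = 1.1, THR = 1.1, LYS = 1.3, MET = 0.45,
  PHE = 0.6, TYR = 0.55,
  G6P = 1.0e-7, F6P = 4e-8, GAP = 2e-8, PEP = 1e-8, PYR = 1e-7,
  CIT = 2e-7, AKG = 5e-8, MAL = 1.5e-7, OAA = 1e-8, R5P = 2e-8,
  GLUin = 2e-6,
  ATP = 3e-6, ADP = 6e-7, AMP = 3e-7,
  NAD = 2e-6, NADH = 2e-7, NADP = 5e-8, NADPH = 2e-7)

metabolites <- c(
  lapply(c("GLC", "GLN", "GLU", "LAC", "NH4", aa[!aa %in% c("GLN", "GLU")]),
         function(id) list(id = id, compartment = "extracellular")),
  lapply(c("G6P", "F6P", "GAP", "PEP", "PYR", "CIT", "AKG", "MAL", "OAA",
           "R5P", "GLUin", "ATP", "ADP", "AMP", "NAD", "NADH", "NADP",
           "NADPH"),
         function(id) list(id = id, compartment = "intracellular")),
  list(list(id = "Xv", compartment = "cells"),
       list(id = "mAb", compartment = "product"),
       list(id = "V", compartment = "volume")))

# ---- biomass / mAb composition ----------------------------------------------
protein_w <- c(ALA = 0.095, ARG = 0.050, ASP = 0.065, ASN = 0.050,
               GLN = 0.050, GLU = 0.070, GLY = 0.085, HIS = 0.022,
               ILE = 0.100, LYS = 0.070, MET = 0.021, PHE = 0.040,
               SER = 0.068, THR = 0.060, TYR = 0.030, VAL = 0.070)
protein_w <- protein_w / sum(protein_w)
mab_w <- c(ALA = 0.050, ARG = 0.035, ASP = 0.050, ASN = 0.045,
           GLN = 0.060, GLU = 0.065, GLY = 0.070, HIS = 0.022,
           ILE = 0.090, LYS = 0.070, MET = 0.012, PHE = 0.040,
           SER = 0.115, THR = 0.090, TYR = 0.045, VAL = 0.095)
mab_w <- mab_w / sum(mab_w)

biomass_mmol <- 2.93e-3          # mmol amino acid per 1e6 new cells
mab_mmol_per_mg <- 9.17e-3       # mmol amino acid per mg mAb
growth_demand <- c(biomass_mmol * protein_w,
                   G6P = 1.6e-4, CIT = 2.2e-4, R5P = 9e-5,
                   ATP = 8e-3, NADPH = 1.35e-3)
mab_demand <- c(mab_mmol_per_mg * mab_w, ATP = 3.7e-2)

# ---- rate-law helpers --------------------------------------------------------
sub  <- function(species, Km) list(species = species, Km = Km)
rsub <- function(num, den, Km) list(ratio = list(num, den), Km = Km)
inh  <- function(effector, K) list(kind = "noncompetitive_inhibition",
                                   effector = effector, K = K)
act  <- function(num, den, Ka, alpha, beta)
  list(kind = "nonessential_activation", ratio = list(num, den),
       Ka = Ka, alpha = alpha, beta = beta)
act_conc <- function(effector, Ka, alpha, beta)
  list(kind = "nonessential_activation", effector = effector,
       Ka = Ka, alpha = alpha, beta = beta)

rx <- function(id, stoich, substrates, regulation = list(), vmax,
               pair = NULL, reconstructed = FALSE) {
  list(id = id, stoichiometry = as.list(stoich),
       rate_law = list(Vmax = vmax,
                       substrates = substrates, regulation = regulation),
       reversible_pair = pair, reconstructed = reconstructed)
}

reactions <- list(
  rx("V_HK", c(GLC = -1, ATP = -1, G6P = 1, ADP = 1),
     list(sub("GLC", "KmGLC_HK"), rsub("ATP", "ADP", "KmATP_ADP")),
     list(inh("G6P", "KdG6P"),
          act("AMP", "ATP", "KaAMP_ATP", "alphaAMP_ATP", "betaAMP_ATP")),
     vmax = "VmaxHK"),
  rx("V_PGI", c(G6P = -1, F6P = 1),
     list(sub("G6P", "KmG6P")),
     list(inh("PEP", "KdPEP_PGI")),
     vmax = "VfmaxPGI", pair = "V_rPGI"),
  rx("V_rPGI", c(F6P = -1, G6P = 1),
     list(sub("F6P", "KmF6P_rPGI")), vmax = "VrmaxPGI", pair = "V_PGI"),
  rx("V_PFK", c(F6P = -1, ATP = -1, GAP = 2, ADP = 1),
     list(sub("F6P", "KmF6P_PFK"), rsub("ATP", "ADP", "KmATP_ADP")),
     list(act("AMP", "ATP", "KaAMP_ATP", "alphaAMP_ATP", "betaAMP_ATP"),
          inh("CIT", "KdCIT_PFK"), inh("LAC", "KdLAC_PFK")),
     vmax = "VmaxPFK"),
  rx("V_PGK", c(GAP = -1, NAD = -1, ADP = -1, PEP = 1, NADH = 1, ATP = 1),
     list(sub("GAP", "KmGAP_PGK"), rsub("NAD", "NADH", "KmNAD_PGK"),
          rsub("ADP", "ATP", "KmADP_ATP")),
     vmax = "VmaxPGK"),
  rx("V_PK", c(PEP = -1, ADP = -1, PYR = 1, ATP = 1),
     list(sub("PEP", "KmPEP_PK"), rsub("ADP", "ATP", "KmADP_ATP")),
     list(act_conc("F6P", "KaF6P_PK", "alphaF6P_PK", "betaF6P_PK"),
          inh("ALA", "KdALA_PK")),
     vmax = "VmaxPK"),
  rx("V_LDH", c(PYR = -1, NADH = -1, LAC = 1, NAD = 1),
     list(sub("PYR", "KmPYR_LDH"), rsub("NADH", "NAD", "KmNADH_LDH")),
     list(act("AMP", "ATP", "KaAMP_ATP", "alphaAMP_ATP", "betaAMP_ATP")),
     vmax = "VmaxLDH", pair = "V_rLDH"),
  rx("V_rLDH", c(LAC = -1, NAD = -1, PYR = 1, NADH = 1),
     list(sub("LAC", "KmLAC_rLDH"), rsub("NAD", "NADH", "KmNAD_rLDH")),
     list(inh("PYR", "KdPYR_rLDH")),
     vmax = "VmaxrLDH", pair = "V_LDH"),
  rx("V_G6PDH", c(G6P = -1, NADP = -2, R5P = 1, NADPH = 2),
     list(sub("G6P", "KmG6P_G6PDH"), rsub("NADP", "NADPH", "KmNADP_G6PDH")),
     vmax = "VmaxG6PDH"),
  rx("V_PDH", c(PYR = -1, OAA = -1, NAD = -1, CIT = 1, NADH = 1),
     list(sub("PYR", "KmPYR_PDH"), sub("OAA", "KmOAA_PDH"),
          rsub("NAD", "NADH", "KmNAD_PDH")),
     vmax = "VmaxPDH", reconstructed = TRUE),
  rx("V_PC", c(PYR = -1, ATP = -1, OAA = 1, ADP = 1),
     list(sub("PYR", "KmPYR_PC"), rsub("ATP", "ADP", "KmATP_ADP")),
     vmax = "VmaxPC"),
  rx("V_IDH", c(CIT = -1, NAD = -1, AKG = 1, NADH = 1),
     list(sub("CIT", "KmCIT_IDH"), rsub("NAD", "NADH", "KmNAD_IDH")),
     vmax = "VmaxIDH", reconstructed = TRUE),
  rx("V_AKGDH", c(AKG = -1, NAD = -2, ADP = -1, MAL = 1, NADH = 2, ATP = 1),
     list(sub("AKG", "KmAKG_AKGDH"), rsub("NAD", "NADH", "KmNAD_AKGDH"),
          rsub("ADP", "ATP", "KmADP_ATP")),
     vmax = "VmaxAKGDH", reconstructed = TRUE),
  rx("V_MLD", c(MAL = -1, NAD = -1, OAA = 1, NADH = 1),
     list(sub("MAL", "KmMAL_MLD"), rsub("NAD", "NADH", "KmNAD_MLD")),
     vmax = "VmaxMLD", reconstructed = TRUE),
  rx("V_ME", c(MAL = -1, NADP = -1, PYR = 1, NADPH = 1),
     list(sub("MAL", "KmMAL_ME"), rsub("NADP", "NADPH", "KmNADP_ME")),
     vmax = "VmaxME", reconstructed = TRUE),
  rx("V_GlnT", c(GLN = -1, GLUin = 1, NH4 = 1),
     list(sub("GLN", "KmGLN_GlnT")),
     vmax = "VfmaxGlnT", pair = "V_rGlnT"),
  rx("V_rGlnT", c(GLUin = -1, NH4 = -1, ATP = -1, GLN = 1, ADP = 1),
     list(sub("GLUin", "KmGLU_rGlnT"), sub("NH4", "KmNH4_rGlnT"),
          rsub("ATP", "ADP", "KmATP_ADP")),
     vmax = "VrmaxGlnT", pair = "V_GlnT"),
  rx("V_GLDH", c(GLUin = -1, NAD = -1, AKG = 1, NADH = 1, NH4 = 1),
     list(sub("GLUin", "KmGLU_GLDH"), rsub("NAD", "NADH", "KmNAD_GLDH")),
     vmax = "VfmaxGLDH", pair = "V_rGLDH"),
  rx("V_rGLDH", c(AKG = -1, NADH = -1, NH4 = -1, GLUin = 1, NAD = 1),
     list(sub("AKG", "KmAKG_rGLDH"), sub("NH4", "KmNH4_rGLDH"),
          rsub("NADH", "NAD", "KmNADH_rGLDH")),
     vmax = "VrmaxGLDH", pair = "V_GLDH"),
  rx("V_ASTA", c(ASP = -1, AKG = -1, OAA = 1, GLUin = 1),
     list(sub("ASP", "KmASP_ASTA"), sub("AKG", "KmAKG_ASTA")),
     vmax = "VmaxASTA"),
  rx("V_AlaTA", c(PYR = -1, GLUin = -1, ALA = 1, AKG = 1),
     list(sub("PYR", "KmPYR_AlaTA"), sub("GLUin", "KmGLU_AlaTA")),
     vmax = "VmaxAlaTA", pair = "V_rAlaTA"),
  rx("V_rAlaTA", c(ALA = -1, AKG = -1, PYR = 1, GLUin = 1),
     list(sub("ALA", "KmALA_rAlaTA"), sub("AKG", "KmAKG_rAlaTA")),
     list(inh("GLN", "KdGLN_rAlaTA")),
     vmax = "VmaxrAlaTA", pair = "V_AlaTA"),
  rx("V_SDHH", c(SER = -1, PYR = 1, NH4 = 1),
     list(sub("SER", "KmSER_SDHH")), vmax = "VmaxSDHH", reconstructed = TRUE),
  rx("V_ASN", c(ASN = -1, ASP = 1, NH4 = 1),
     list(sub("ASN", "KmASN_ASN")), vmax = "VmaxASN"),
  rx("V_AAtoSUC",
     c(ILE = -1, VAL = -1, THR = -1, LYS = -1, MET = -1, MAL = 5),
     list(sub("ILE", "KmILE_AAtoSUC"), sub("VAL", "KmVAL_AAtoSUC"),
          sub("THR", "KmTHR_AAtoSUC"), sub("LYS", "KmLYS_AAtoSUC"),
          sub("MET", "KmMET_AAtoSUC")),
     vmax = "VmaxAAtoSUC", reconstructed = TRUE),
  rx("V_HISARGTA", c(HIS = -1, ARG = -1, AKG = 2, NH4 = 2),
     list(sub("HIS", "KmHIS_HISARGTA"), sub("ARG", "KmARG_HISARGTA")),
     vmax = "VmaxHISARGTA", reconstructed = TRUE),
  rx("V_GluT", c(GLUin = -1, GLU = 1),
     list(sub("GLUin", "KmGLU_GluT")),
     vmax = "VfmaxGluT", pair = "V_rGluT"),
  rx("V_rGluT", c(GLU = -1, GLUin = 1),
     list(sub("GLU", "KmGLU_rGluT")),
     vmax = "VrmaxGluT", pair = "V_GluT"),
  rx("V_resp", c(NADH = -2, NAD = 2, ADP = -5, ATP = 5),
     list(rsub("NADH", "NAD", "KmNADH"), rsub("ADP", "ATP", "KmADP_ATP")),
     vmax = "Vmaxresp"),
  rx("V_leak", c(NADH = -1, NAD = 1),
     list(rsub("NADH", "NAD", "KmNADH_leak")), vmax = "Vmaxleak"),
  rx("V_ATPase", c(ATP = -1, ADP = 1),
     list(rsub("ATP", "ADP", "KmATP")), vmax = "VmaxATPase"),
  rx("V_fAK", c(ADP = -2, ATP = 1, AMP = 1),
     list(rsub("ADP", "ATP", "KmADP_ATP")),
     vmax = "VfmaxAK", pair = "V_rAK"),
  rx("V_rAK", c(ATP = -1, AMP = -1, ADP = 2),
     list(rsub("AMP", "ATP", "KmAMP_rAK")),
     vmax = "VrmaxAK", pair = "V_fAK"))

# growth: all extracellular amino acids + G6P, CIT, R5P precursors, lactate
# and ammonia inhibition; consumes biomass demands, produces cells
growth_stoich <- c(-growth_demand[aa],
                   G6P = unname(-growth_demand["G6P"]),
                   CIT = unname(-growth_demand["CIT"]),
                   R5P = unname(-growth_demand["R5P"]),
                   ATP = unname(-growth_demand["ATP"]),
                   ADP = unname(growth_demand["ATP"]),
                   NADPH = unname(-growth_demand["NADPH"]),
                   NADP = unname(growth_demand["NADPH"]),
                   Xv = 1)
names(growth_stoich)[seq_along(aa)] <- aa
growth_subs <- c(
  lapply(aa, function(a) sub(a, paste0("Km", a, "growth"))),
  list(sub("G6P", "KmG6Pgrowth"), sub("CIT", "KmCITgrowth"),
       sub("R5P", "KmR5Pgrowth"),
       # energy/redox saturation: anabolism stalls when ATP or NADPH runs out
       rsub("ATP", "ADP", "KmATPgrowth"),
       rsub("NADPH", "NADP", "KmNADPHgrowth")))
reactions <- c(reactions, list(
  rx("V_growth", growth_stoich, growth_subs,
     list(inh("LAC", "KdLACgrowth"), inh("NH4", "KdNH4growth")),
     vmax = "Vmaxgrowth")))

mab_stoich <- c(-mab_demand[aa],
                ATP = unname(-mab_demand["ATP"]),
                ADP = unname(mab_demand["ATP"]),
                mAb = 1)
names(mab_stoich)[seq_along(aa)] <- aa
mab_subs <- c(lapply(aa, function(a) sub(a, paste0("Km", a, "mAb"))),
              list(rsub("ATP", "ADP", "KmATPmAb")))
reactions <- c(reactions, list(
  rx("V_mAb", mab_stoich, mab_subs, vmax = "VmaxmAb")))

network <- list(
  name = "cho-mab-reference",
  description = paste(
    "Reconstructed (synthetic) reference network for mAb-producing CHO cells:",
    "glycolysis, TCA cycle, pentose phosphate pathway, amino acid metabolism,",
    "oxidative phosphorylation and energetics. ILE is the pooled ILE+LEU",
    "species. Reactions flagged 'reconstructed' have grammar-consistent",
    "minimal rate laws where the published supplementary equations were not",
    "available."),
  biomass = list(
    dry_weight_g_per_1e6 = 3.15e-4,
    protein_mw = 107.5,
    biomass_mmol_per_1e6 = biomass_mmol,
    mab_mmol_per_mg = mab_mmol_per_mg,
    growth_demand = as.list(growth_demand),
    mab_demand = as.list(mab_demand)),
  metabolites = metabolites,
  reactions = reactions)

yaml::write_yaml(network, file.path(out_dir, "cho_network.yaml"),
                 precision = 12)

# ---- parameter values --------------------------------------------------------
km <- c(
  KmGLC_HK = 2.0, KmATP_ADP = 1.0, KdG6P = 1.5e-7,
  KaAMP_ATP = 0.09, alphaAMP_ATP = 0.4, betaAMP_ATP = 2.5,
  KmG6P = 2.9e-8, KdPEP_PGI = 2e-8, KmF6P_rPGI = 6e-8,
  KmF6P_PFK = 4e-8, KdCIT_PFK = 3e-7, KdLAC_PFK = 14,
  KmGAP_PGK = 3e-8, KmNAD_PGK = 2.0, KmADP_ATP = 0.05,
  KmPEP_PK = 1.5e-8, KaF6P_PK = 5e-8, alphaF6P_PK = 0.5, betaF6P_PK = 2.0,
  KdALA_PK = 7.0,
  KmPYR_LDH = 1.5e-7, KmNADH_LDH = 0.05,
  KmLAC_rLDH = 12, KmNAD_rLDH = 2.0, KdPYR_rLDH = 8e-8,
  KmG6P_G6PDH = 1.2e-7, KmNADP_G6PDH = 0.3,
  KmPYR_PDH = 1.2e-7, KmOAA_PDH = 8e-9, KmNAD_PDH = 2.0,
  KmPYR_PC = 2e-7,
  KmCIT_IDH = 2.5e-7, KmNAD_IDH = 2.0,
  KmAKG_AKGDH = 6e-8, KmNAD_AKGDH = 2.0,
  KmMAL_MLD = 2e-7, KmNAD_MLD = 2.0,
  KmMAL_ME = 2e-7, KmNADP_ME = 0.3,
  KmGLN_GlnT = 1.0,
  KmGLU_rGlnT = 3e-6, KmNH4_rGlnT = 2.0,
  KmGLU_GLDH = 4e-6, KmNAD_GLDH = 2.0,
  KmAKG_rGLDH = 8e-8, KmNH4_rGLDH = 3.0, KmNADH_rGLDH = 0.1,
  KmASP_ASTA = 0.5, KmAKG_ASTA = 8e-8,
  KmPYR_AlaTA = 1.5e-7, KmGLU_AlaTA = 3e-6,
  KmALA_rAlaTA = 1.0, KmAKG_rAlaTA = 8e-8, KdGLN_rAlaTA = 0.3,
  KmSER_SDHH = 1.0, KmASN_ASN = 1.0,
  KmILE_AAtoSUC = 0.5, KmVAL_AAtoSUC = 0.5, KmTHR_AAtoSUC = 0.5,
  KmLYS_AAtoSUC = 0.5, KmMET_AAtoSUC = 0.3,
  KmHIS_HISARGTA = 0.3, KmARG_HISARGTA = 0.5,
  KmGLU_GluT = 4e-6, KmGLU_rGluT = 1.0,
  KmNADH = 0.05, KmNADH_leak = 0.2, KmATP = 4.0, KmAMP_rAK = 0.15,
  KdLACgrowth = 100, KdNH4growth = 5,
  KmG6Pgrowth = 2e-8, KmCITgrowth = 4e-8, KmR5Pgrowth = 5e-9,
  KmATPgrowth = 0.5, KmNADPHgrowth = 0.4, KmATPmAb = 0.5)
growth_km <- setNames(
  c(0.03, 0.05, 0.04, 0.05, 0.06, 0.05, 0.03, 0.02, 0.06,
    0.05, 0.02, 0.03, 0.04, 0.04, 0.03, 0.05),
  paste0("Km", aa, "growth"))
mab_km <- setNames(
  c(0.04, 0.06, 0.05, 0.06, 0.08, 0.06, 0.04, 0.03, 0.07,
    0.06, 0.03, 0.04, 0.05, 0.05, 0.04, 0.06),
  paste0("Km", aa, "mAb"))
km <- c(km, growth_km, mab_km)

# target nominal fluxes (mmol/1e6 cells/h; V_growth 1/h, V_mAb mg/1e6 cells/h)
target_flux <- c(
  V_HK = 2.0e-4, V_PGI = 2.0e-4, V_rPGI = 2.0e-5, V_PFK = 1.8e-4,
  V_PGK = 3.6e-4, V_PK = 3.5e-4, V_LDH = 2.9e-4, V_rLDH = 5e-6,
  V_G6PDH = 3.5e-6, V_PDH = 1.6e-5, V_PC = 2.0e-6, V_IDH = 8.0e-6,
  V_AKGDH = 4.0e-5, V_MLD = 1.4e-5, V_ME = 4.0e-5,
  V_GlnT = 3.0e-5, V_rGlnT = 1.0e-6, V_GLDH = 1.0e-6, V_rGLDH = 5.0e-7,
  V_ASTA = 2.0e-6, V_AlaTA = 3.0e-5, V_rAlaTA = 1.5e-6,
  V_SDHH = 2.0e-6, V_ASN = 3.0e-6, V_AAtoSUC = 2.0e-6, V_HISARGTA = 1.0e-6,
  V_GluT = 2.0e-6, V_rGluT = 1.0e-6,
  V_resp = 8.0e-5, V_leak = 3.0e-5, V_ATPase = 4.5e-4,
  V_fAK = 2.0e-5, V_rAK = 2.0e-5,
  V_growth = 0.035, V_mAb = 2.0e-4)

net <- load_network(file.path(out_dir, "cho_network.yaml"))
vmax_names <- vapply(net$reactions, function(r) r$rate_law$Vmax, "")
stopifnot(setequal(names(target_flux), names(vmax_names)))

# solve Vmax: evaluate each rate law with Vmax = 1 at the nominal state
unit_v <- setNames(rep(1, length(vmax_names)), vmax_names)
p_probe <- c(unit_v, km)
fl_unit <- flux_vector(net, nominal, p_probe)
vmax <- target_flux[names(vmax_names)] / fl_unit[names(vmax_names)]
names(vmax) <- vmax_names

params <- c(vmax, km)
sensitive <- c("Vmaxgrowth", "VmaxPK", "VrmaxAK", "VmaxPGK", "Vmaxresp",
               "VfmaxAK", "VmaxHK", "VmaxATPase", "KmATP", "KmADP_ATP",
               "KmNADH", "KdNH4growth", "KmG6P", "alphaAMP_ATP",
               "VfmaxGlnT", "betaAMP_ATP", "Vmaxleak", "VfmaxPGI",
               "KaAMP_ATP", "KdG6P")
stopifnot(all(sensitive %in% names(params)))
ptab <- data.frame(
  name = names(params),
  value = unname(params),
  magnitude_exponent = floor(log10(unname(params))),
  lower_bound = 0,
  upper_bound = Inf,
  sensitive_flag = as.integer(names(params) %in% sensitive))
write.csv(ptab, file.path(out_dir, "cho_parameters.csv"), row.names = FALSE)

# ---- culture experiments -----------------------------------------------------
intr0 <- nominal[c("G6P", "F6P", "GAP", "PEP", "PYR", "CIT", "AKG", "MAL",
                   "OAA", "R5P", "GLUin", "ATP", "ADP", "AMP", "NAD", "NADH",
                   "NADP", "NADPH")]
biogro_aa <- c(ALA = 0.35, ASP = 0.35, ASN = 1.2, SER = 0.9, GLY = 0.7,
               HIS = 0.5, ARG = 1.4, ILE = 1.6, VAL = 1.1, THR = 1.1,
               LYS = 1.3, MET = 0.45, PHE = 0.6, TYR = 0.55, GLU = 0.5)
powercho_aa <- c(ALA = 0.45, ASP = 1.1, ASN = 3.2, SER = 2.4, GLY = 0.8,
                 HIS = 0.7, ARG = 2.4, ILE = 2.6, VAL = 1.5, THR = 1.4,
                 LYS = 1.7, MET = 0.6, PHE = 0.8, TYR = 0.7, GLU = 0.7)

make_experiment <- function(name, medium, mode, glc0, gln0, aa0, nh4_0,
                            duration, sampling, feed = NULL) {
  init <- c(list(Xv = 0.2, V = 1.0, mAb = 0, GLC = glc0, GLN = gln0,
                 LAC = 0.1, NH4 = nh4_0),
            as.list(aa0), as.list(intr0))
  ex <- list(name = name, medium = medium, mode = mode, duration = duration,
             sampling_interval = sampling, initial = init)
  if (!is.null(feed)) ex$feed <- feed
  ex
}
write_exp <- function(ex, file) {
  yaml::write_yaml(ex, file.path(out_dir, file), precision = 12)
}

write_exp(make_experiment("biogro_batch", "Biogro-CHO", "batch",
                          glc0 = 25, gln0 = 4, biogro_aa, nh4_0 = 0.22,
                          duration = 144, sampling = 12),
          "experiment_biogro_batch.yaml")
write_exp(make_experiment("biogro_fedbatch", "Biogro-CHO", "fed-batch",
                          glc0 = 10, gln0 = 2.4, biogro_aa, nh4_0 = 0.22,
                          duration = 192, sampling = 24,
                          feed = list(
                            composition = list(GLC = 130, GLN = 25),
                            policy = list(interval = 24, start = 24,
                                          glucose_floor = 10, set_point = 10 + 5,
                                          conditional = FALSE))),
          "experiment_biogro_fedbatch.yaml")
# PowerCHO-2 base glucose is not printed in the main text; 40 mM is a
# reconstructed value (the 2.5x concentrate carries 100 mM).
powercho_feed_comp <- c(list(GLC = 100, GLN = 16),
                        as.list(powercho_aa * 2.5))
write_exp(make_experiment("powercho_batch", "PowerCHO-2", "batch",
                          glc0 = 40, gln0 = 6.5, powercho_aa, nh4_0 = 0.18,
                          duration = 216, sampling = 24),
          "experiment_powercho_batch.yaml")
write_exp(make_experiment("powercho_fedbatch", "PowerCHO-2", "fed-batch",
                          glc0 = 40, gln0 = 6.5, powercho_aa, nh4_0 = 0.18,
                          duration = 360, sampling = 24,
                          feed = list(
                            composition = powercho_feed_comp,
                            policy = list(interval = 24, start = 24,
                                          glucose_floor = 10, set_point = 40,
                                          conditional = FALSE))),
          "experiment_powercho_fedbatch.yaml")

# ---- published full-model screening ranks (fixture for subset selection) -----
ref_sens <- data.frame(
  parameter = sensitive,
  mean_ee = c(4.6, 1.7, 1.6, 1.4, 1.4, 1.3, 1.3, 1.2, 1.1, 1.1,
              0.9, 0.9, 0.9, 0.8, 0.7, 0.6, 0.6, 0.6, 0.6, 0.6),
  sd_ee = c(6.9, 4.1, 3.6, 3.5, 3.6, 2.9, 3.3, 4.7, 4.0, 2.6,
            3.1, 3.4, 3.4, 2.5, 3.1, 2.5, 1.6, 2.1, 1.7, 1.7))
write.csv(ref_sens, file.path(out_dir, "reference_sensitivity.csv"),
          row.names = FALSE)

# ---- derived flux quantities (data-driven definitions) -----------------------
derived <- list(
  sums = list(
    ammonia_production = list(V_GLDH = 1, V_GlnT = 1, V_SDHH = 1,
                              V_ASN = 1, V_HISARGTA = 1),
    tca_influx = list(V_GLDH = 1, V_PDH = 1, V_AlaTA = 1, V_PC = 1,
                      V_AAtoSUC = 5),
    net_atp_production = list(V_PGK = 1, V_PK = 1, V_AKGDH = 1, V_PC = 1,
                              V_GlnT = 1, V_resp = 5),
    aa_to_tca = list(V_GLDH = 1, V_AlaTA = 1, V_AAtoSUC = 5),
    glycolytic_atp = list(V_HK = 1, V_PFK = 1),
    respiratory_atp = list(V_resp = 5)),
  ratios = list(
    aa_contribution_tca = list(num = "aa_to_tca", den = "tca_influx"),
    pdh_contribution_tca = list(num = "V_PDH", den = "tca_influx"),
    pc_contribution_tca = list(num = "V_PC", den = "tca_influx"),
    atp_from_glycolysis = list(num = "glycolytic_atp",
                               den = "net_atp_production"),
    atp_from_respiration = list(num = "respiratory_atp",
                                den = "net_atp_production"),
    pdh_to_pk = list(num = "V_PDH", den = "V_PK"),
    ldh_to_pk = list(num = "V_LDH", den = "V_PK")))
yaml::write_yaml(derived, file.path(out_dir, "derived_fluxes.yaml"))

# ---- toy network (fast oracle tests) -----------------------------------------
toy <- list(
  name = "toy-uptake-chain",
  description = paste(
    "Three-reaction toy model: substrate uptake into a per-cell intermediate,",
    "conversion to a secreted product with product inhibition, and first-order",
    "like degradation. Used for fast calibration / recovery oracles."),
  biomass = NULL,
  metabolites = list(
    list(id = "S", compartment = "extracellular"),
    list(id = "Q", compartment = "extracellular"),
    list(id = "P", compartment = "intracellular"),
    list(id = "Xv", compartment = "cells"),
    list(id = "V", compartment = "volume")),
  reactions = list(
    rx("V_upt", c(S = -1, P = 1), list(sub("S", "KmS_upt")),
       vmax = "Vmax_upt"),
    rx("V_conv", c(P = -1, Q = 1), list(sub("P", "KmP_conv")),
       list(inh("Q", "KdQ_conv")), vmax = "Vmax_conv"),
    rx("V_deg", c(P = -1), list(sub("P", "KmP_deg")),
       vmax = "Vmax_deg")))
yaml::write_yaml(toy, file.path(out_dir, "toy_network.yaml"), precision = 12)

toy_params <- c(Vmax_upt = 2e-4, KmS_upt = 1.0,
                Vmax_conv = 3e-4, KmP_conv = 1e-7, KdQ_conv = 20,
                Vmax_deg = 5e-5, KmP_deg = 2e-7)
toy_tab <- data.frame(
  name = names(toy_params),
  value = unname(toy_params),
  magnitude_exponent = floor(log10(unname(toy_params))),
  lower_bound = 0, upper_bound = Inf,
  sensitive_flag = as.integer(names(toy_params) %in%
                                c("Vmax_upt", "Vmax_conv", "KmS_upt")))
write.csv(toy_tab, file.path(out_dir, "toy_parameters.csv"), row.names = FALSE)

write_exp(list(name = "toy_batch", medium = "toy", mode = "batch",
               duration = 72, sampling_interval = 6,
               initial = list(S = 20, Q = 0, P = 1e-7, Xv = 1.0, V = 1.0)),
          "toy_experiment.yaml")

cat("reference model written to", out_dir, "\n")
rep <- validate_network(net, load_parameters(file.path(out_dir, "cho_parameters.csv")))
print(rep$issues)
cat("parameters used by model:", rep$n_parameters, "\n")
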