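# Builds the plain-text reference fixtures under inst/extdata/.
# Gene sets and drug-target cells are transcribed from the published PAD
# repositioning tables; decoy relation rows and the small networks are
# synthetic and labelled as such in the emitted files.
# Run from the package root: Rscript data-raw/fixtures.R

anti_angiogenic <- c(
  "AMOT", "ANGPT2", "APOH", "BAI1", "CCL2", "CCR2", "COL4A2", "COL4A3",
  "CXCL10", "FASLG", "FOXO4", "GHRL", "GTF2I", "HDAC5", "HHEX", "HOXA5",
  "HRG", "KLF4", "KLK3", "KRIT1", "LECT1", "LIF", "MAP2K5", "NF1", "NPPB",
  "NPR1", "PDE3B", "PF4", "PML", "PTPRM", "ROCK1", "ROCK2", "SERPINE1",
  "SERPINF1", "STAB1", "THBS1", "THBS2", "THBS4", "TIE1"
)
stopifnot(length(anti_angiogenic) == 39)

pro_inflammatory <- c(
  "ACE", "ADAM8", "ADORA2B", "ADORA3", "AGER", "AGT", "AGTR1", "ALOX5AP",
  "AOC3", "C3", "CCL24", "CCL3", "CCL3L3", "CCL5", "CCR2", "CCR5", "CCR7",
  "CD28", "CD47", "CLOCK", "CNR1", "CTSS", "CX3CL1", "EDNRA", "EGFR",
  "FABP4", "FCER1A", "FCER1G", "FCGR1A", "FCGR2A", "FFAR3", "GPRC5B",
  "HSPD1", "HYAL2", "IDO1", "IL12B", "IL15", "IL18", "IL1B", "IL1RL1",
  "IL2", "IL21", "IL23A", "IL33", "IL6", "IL6ST", "ITGA2", "JAK2", "LBP",
  "LTA", "MAPK13", "MIF", "NLRP12", "NPY5R", "OSM", "OSMR", "PDE2A",
  "PDE5A", "PIK3CG", "PLA2G2A", "PLA2G4A", "PLA2G7", "PRKCA", "PTGER3",
  "PTGER4", "PTGS2", "RPS19", "S100A12", "S100A8", "S100A9", "SERPINE1",
  "STAT5A", "STAT5B", "TAC1", "TGM2", "TLR2", "TLR3", "TLR4", "TLR7",
  "TLR9", "TLR10", "TNF", "TNFRSF11A", "TNFRSF1A", "TNFSF11", "TNFSF4",
  "TNIP1", "WNT5A", "ZP3"
)
stopifnot(length(pro_inflammatory) == 89)

gmt <- c(
  paste(c("GO:0016525", "negative regulation of angiogenesis",
          anti_angiogenic), collapse = "\t"),
  paste(c("GO:0050729", "positive regulation of inflammatory response",
          pro_inflammatory), collapse = "\t")
)
writeLines(gmt, "inst/extdata/strategy_gene_sets.gmt")

# Approved drug -> target cells, one list element per target gene.
# Duplicate names inside a cell are kept as printed (the parser deduplicates).
proangio_targets <- list(
  CCL2     = c("Mimosine", "danazol"),
  NPPB     = c("Carvedilol"),
  NPR1     = c("Nitroprusside", "nitroglycerin", "isosorbide dinitrate",
               "amyl nitrite", "erythrityl tetranitrate", "nesiritide"),
  PF4      = c("Drotrecogin alfa"),
  SERPINE1 = c("Alteplase", "urokinase", "reteplase", "anistreplase",
               "tenecteplase", "drotrecogin alfa")
)

antiinfl_targets <- list(
  ACE      = c("Ramipril", "fosinopril", "trandolapril", "benazepril",
               "enalapril", "candoxatril", "moexipril", "lisinopril",
               "perindopril", "quinapril", "rescinnamine", "captopril",
               "cilazapril", "spirapril"),
  ADORA2B  = c("Theophylline", "adenosine", "enprofylline", "defibrotide"),
  AGTR1    = c("Valsartan", "olmesartan", "losartan", "candesartan",
               "eprosartan", "telmisartan", "irbesartan", "forasartan",
               "saprisartan", "tasosartan"),
  AOC3     = c("Phenelzine", "hydralazine"),
  C3       = c("Intravenous immunoglobulin"),
  CCR5     = c("Maraviroc"),
  CNR1     = c("Dronabinol", "nabilone", "rimonabant", "dronabinol"),
  EDNRA    = c("Bosentan", "sitaxentan"),
  EGFR     = c("Cetuximab", "trastuzumab", "lidocaine", "gefitinib",
               "erlotinib", "lapatinib", "panitumumab"),
  FCER1A   = c("Omalizumab", "benzylpenicilloyl polylysine"),
  FCER1G   = c("Benzylpenicilloyl polylysine"),
  FCGR1A   = c("Cetuximab", "etanercept", "intravenous immunoglobulin",
               "adalimumab", "abciximab", "gemtuzumab ozogamicin",
               "trastuzumab", "rituximab", "basiliximab", "muromonab",
               "ibritumomab", "tositumomab", "alemtuzumab", "alefacept",
               "efalizumab", "natalizumab", "palivizumab", "daclizumab",
               "bevacizumab", "porfimer"),
  FCGR2A   = c("Cetuximab", "etanercept", "intravenous immunoglobulin",
               "adalimumab", "abciximab", "gemtuzumab ozogamicin",
               "trastuzumab", "rituximab", "basiliximab", "muromonab",
               "ibritumomab", "tositumomab", "alemtuzumab", "alefacept",
               "efalizumab", "natalizumab", "palivizumab", "daclizumab",
               "bevacizumab"),
  IL1B     = c("Minocycline", "gallium nitrate", "canakinumab"),
  IL6      = c("Ginseng"),
  LTA      = c("Etanercept"),
  PDE5A    = c("Sildenafil", "theophylline", "pentoxifylline", "tadalafil",
               "vardenafil", "dipyridamole", "udenafil"),
  PLA2G2A  = c("Indomethacin", "diclofenac", "ginkgo biloba", "suramin",
               "ginkgo biloba"),
  PLA2G4A  = c("Fluticasone propionate", "quinacrine"),
  PRKCA    = c("Phosphatidylserine", "vitamin E"),
  PTGER3   = c("Bimatoprost", "dinoprostone", "misoprostol"),
  PTGS2    = c("Gamma-homolinolenic acid", "icosapent",
               "aminosalicylic acid", "mesalazine", "acetaminophen",
               "indomethacin", "nabumetone", "ketorolac", "tenoxicam",
               "lenalidomide", "celecoxib", "tolmetin", "piroxicam",
               "fenoprofen", "diclofenac", "sulindac", "flurbiprofen",
               "etodolac", "mefenamic acid", "naproxen", "sulfasalazine",
               "phenylbutazone", "meloxicam", "carprofen", "diflunisal",
               "suprofen", "salicyclic acid", "meclofenamic acid",
               "acetylsalicylic acid", "bromfenac", "oxaprozin",
               "ketoprofen", "balsalazide", "thalidomide", "ibuprofen",
               "lumiracoxib", "magnesium salicylate", "salicylate-sodium",
               "salsalate", "trisalicylate-choline", "ginseng",
               "antrafenine", "antipyrine", "tiaprofenic acid",
               "etoricoxib", "niflumic acid", "lornoxicam", "nepafenac",
               "gamma-homolinolenic acid", "icosapent", "ginseng",
               "thalidomide"),
  S100A12  = c("Olopatadine", "amlexanox"),
  SERPINE1 = c("Alteplase", "urokinase", "reteplase", "anistreplase",
               "tenecteplase", "drotrecogin alfa"),
  STAT5B   = c("Dasatinib"),
  TLR2     = c("Ospa lipoprotein"),
  TLR7     = c("Imiquimod", "hydroxychloroquine"),
  TLR9     = c("Chloroquine", "hydroxychloroquine"),
  TNF      = c("Etanercept", "adalimumab", "infliximab", "chloroquine",
               "thalidomide", "glucosamine", "clenbuterol", "pranlukast",
               "amrinone", "thalidomide"),
  TNFSF11  = c("Lenalidomide")
)
stopifnot(length(antiinfl_targets) == 30)

pairs <- rbind(
  do.call(rbind, lapply(names(proangio_targets), function(g)
    data.frame(gene = g, drug_name = proangio_targets[[g]]))),
  do.call(rbind, lapply(names(antiinfl_targets), function(g)
    data.frame(gene = g, drug_name = antiinfl_targets[[g]])))
)
key <- tolower(trimws(pairs$drug_name))
ids <- setNames(sprintf("DB%04d", seq_along(unique(key))), unique(key))
pairs$drug_id <- ids[key]

db_lines <- c(
  "# DrugBank-dialect relation fixture for PAD drug repositioning.",
  "# drug_target rows: approved drug -> target cells from the published",
  "# pro-angiogenic and anti-inflammatory candidate tables.",
  "# Rows below the 'synthetic decoys' marker are synthetic.",
  paste("relation_type", "drug_id", "drug_name", "groups", "partner",
        sep = "\t"),
  sprintf("drug_target\t%s\t%s\tapproved\t%s",
          pairs$drug_id, pairs$drug_name, pairs$gene),
  "# --- synthetic decoys below this line ---",
  "drug_target\tDBX001\tDecoyin\texperimental\tTHBS1",
  "drug_target\tDBX002\tWithdrawnol\twithdrawn\tROCK1",
  "drug_target\tDBX003\tTrialozole\texperimental;illicit\tTNF",
  "drug_target\tDBX004\tClotinase\tapproved\tF2",
  "drug_target\tDBX005\tAdhesimab\tapproved\tVCAM1",
  "drug_target\tDBX006\tNutraceutol\tnutraceutical\tHRG",
  "drug_gene\tDB0003\tCarvedilol\tapproved\tSERPINF1",
  "drug_gene\tDBX004\tClotinase\tapproved\tTHBS2",
  "drug_drug\tDB0003\tCarvedilol\tapproved\tDB0010",
  "drug_drug\tDBX004\tClotinase\tapproved\tDB0014"
)
writeLines(db_lines, "inst/extdata/drugbank_pad.tsv")

pg_lines <- c(
  "# PharmGKB-dialect relation fixture (synthetic associated-gene sample).",
  paste("relation_type", "gene", "drug_id", "drug_name", "partner",
        sep = "\t"),
  "gene_drug\tACE\tPA0001\tlisinopril\t",
  "gene_drug\tPTGS2\tPA0002\tcelecoxib\t",
  "gene_drug\tSERPINE1\tPA0003\turokinase\t",
  "gene_drug\tTHBS1\tPA0004\tassocimycin\t",
  "gene_drug\tAGTR1\tPA0005\tlosartan\t",
  "gene_disease\tSERPINE1\t\t\tperipheral arterial disease",
  "gene_disease\tACE\t\t\thypertension",
  "gene_gene\tTNF\t\t\tIL6",
  "gene_gene\tSERPINE1\t\t\tPLAT"
)
writeLines(pg_lines, "inst/extdata/pharmgkb_pad.tsv")

# Mechanism-of-action annotation tables (tidy: one row per drug-target pair)
# with the published per-network degree of each target.
mech_pro <- c(
  paste("drug_name", "target", "degree_angiome", "mechanism",
        "original_use", sep = "\t"),
  "Alteplase\tSERPINE1\t14\tPlasminogen activator\tAcute ischemic stroke",
  "Danazol\tCCL2\t12\tSynthetic steroid with antigonadotropic and anti-estrogenic activities\tEndometriosis",
  "Nitroprusside\tNPR1\t4\tA source of nitric oxide, a potent peripheral vasodilator\tHypertensive emergency",
  "Isosorbide dinitrate\tNPR1\t4\tVasodilator\tAngina pectoris",
  "Nesiritide\tNPR1\t4\tRecombinant form of brain natriuretic peptide\tHeart failure",
  "Carvedilol\tNPPB\t3\tBeta-1 and beta-2 adrenergic receptors blocker\tCongestive heart failure"
)
writeLines(mech_pro, "inst/extdata/mechanism_pro_angiogenic.tsv")

mech_anti_rows <- list(
  c("Lapatinib", "EGFR", 137), c("Lidocaine", "EGFR", 137),
  c("Maraviroc", "CCR5", 46), c("Dasatinib", "STAT5B", 33),
  c("Chloroquine", "TNF", 22), c("Chloroquine", "TLR9", 22),
  c("Clenbuterol", "TNF", 22), c("Glucosamine", "TNF", 22),
  c("Infliximab", "TNF", 22), c("Alteplase", "SERPINE1", 18),
  c("Intravenous immunoglobulin", "C3", 30),
  c("Intravenous immunoglobulin", "FCGR1A", 13),
  c("Intravenous immunoglobulin", "FCGR2A", 11),
  c("Drotrecogin alfa", "SERPINE1", 18),
  c("Candesartan", "AGTR1", 16), c("Eprosartan", "AGTR1", 16),
  c("Irbesartan", "AGTR1", 16), c("Losartan", "AGTR1", 16),
  c("Olmesartan", "AGTR1", 16), c("Telmisartan", "AGTR1", 16),
  c("Valsartan", "AGTR1", 16),
  c("Adalimumab", "FCGR1A", 13), c("Adalimumab", "FCGR2A", 11),
  c("Adalimumab", "TNF", 22),
  c("Lenalidomide", "TNFSF11", 15),
  c("Thalidomide", "PTGS2", 7), c("Thalidomide", "TNF", 22),
  c("Etanercept", "FCGR1A", 13), c("Etanercept", "FCGR2A", 11),
  c("Etanercept", "LTA", 7), c("Etanercept", "TNF", 22),
  c("Abciximab", "FCGR1A", 13), c("Abciximab", "FCGR2A", 11),
  c("Alefacept", "FCGR1A", 13), c("Alefacept", "FCGR2A", 11),
  c("Alemtuzumab", "FCGR1A", 13), c("Alemtuzumab", "FCGR2A", 11),
  c("Daclizumab", "FCGR1A", 13), c("Daclizumab", "FCGR2A", 11),
  c("Efalizumab", "FCGR1A", 13), c("Efalizumab", "FCGR2A", 11),
  c("Rituximab", "FCGR1A", 13), c("Rituximab", "FCGR2A", 11),
  c("Canakinumab", "IL1B", 10), c("Gallium nitrate", "IL1B", 10),
  c("Minocycline", "IL1B", 10),
  c("Aminosalicylic acid", "PTGS2", 7), c("Balsalazide", "PTGS2", 7),
  c("Acetaminophen", "PTGS2", 7), c("Acetylsalicylic acid", "PTGS2", 7),
  c("Bromfenac", "PTGS2", 7), c("Etodolac", "PTGS2", 7),
  c("Etoricoxib", "PTGS2", 7), c("Gamma-homolinolenic acid", "PTGS2", 7),
  c("Carprofen", "PTGS2", 7), c("Celecoxib", "PTGS2", 7),
  c("Ibuprofen", "PTGS2", 7), c("Ketoprofen", "PTGS2", 7),
  c("Ketorolac", "PTGS2", 7), c("Lornoxicam", "PTGS2", 7),
  c("Mefenamic acid", "PTGS2", 7), c("Meloxicam", "PTGS2", 7),
  c("Mesalazine", "PTGS2", 7), c("Nabumetone", "PTGS2", 7),
  c("Naproxen", "PTGS2", 7), c("Nepafenac", "PTGS2", 7),
  c("Niflumic acid", "PTGS2", 7), c("Piroxicam", "PTGS2", 7),
  c("Salsalate", "PTGS2", 7), c("Sulindac", "PTGS2", 7),
  c("Tenoxicam", "PTGS2", 7),
  c("Indomethacin", "PTGS2", 7), c("Indomethacin", "PLA2G2A", 6),
  c("Suramin", "PLA2G2A", 6),
  c("Bosentan", "EDNRA", 4), c("Omalizumab", "FCER1A", 3),
  c("Enazepril", "ACE", 2), c("Captopril", "ACE", 2),
  c("Dinoprostone", "PTGER3", 2), c("Dipyridamole", "PDE5A", 2),
  c("Enalapril", "ACE", 2), c("Misoprostol", "PTGER3", 2),
  c("Pentoxifylline", "PDE5A", 2), c("Perindopril", "ACE", 2),
  c("Quinapril", "ACE", 2), c("Bildenafil", "PDE5A", 2),
  c("Tadalafil", "PDE5A", 2), c("Theophylline", "PDE5A", 2),
  c("Theophylline", "ADORA2B", 2), c("Vardenafil", "PDE5A", 2),
  c("Hydralazine", "AOC3", 1)
)
mech_anti <- c(
  paste("drug_name", "target", "degree_immunome", sep = "\t"),
  vapply(mech_anti_rows, function(r) paste(r, collapse = "\t"), "")
)
writeLines(mech_anti, "inst/extdata/mechanism_anti_inflammatory.tsv")

# Synthetic stand-in network: SERPINE1 hub with 14 interactors plus a few
# peripheral edges (the real angiome is external supplementary data).
leaves <- c("PLAT", "PLAU", "PLG", "F2", "FN1", "VTN", "TGFB1", "VEGFA",
            "EGF", "IGF1", "IL6", "TNF", "CCL2", "NPPB")
net_lines <- c(
  "# Synthetic angiome-like stand-in network (SERPINE1 hub, degree 14).",
  paste("SERPINE1", leaves, sep = "\t"),
  "PLAT\tPLAU", "PLAU\tPLG", "TNF\tIL6", "CCL2\tIL6", "VEGFA\tFN1"
)
writeLines(net_lines, "inst/extdata/network_angiome_synthetic.tsv")

print(tools::md5sum(list.files("inst/extdata", full.names = TRUE)))
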