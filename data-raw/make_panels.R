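# Generates the packaged synthetic role panels (inst/extdata/*.tsv).
# Run once from the package root: Rscript data-raw/make_panels.R
# The proteins are synthetic stand-ins; a handful of hydrolase residues are
# fixed so that the frameshift-locus codon layout in R/synthetic.R can
# realise the planted junction motifs without changing the encoded protein.

set.seed(20230516)

aa20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
# rough bacterial proteome residue frequencies
freq <- c(A=8.9, R=5.5, N=3.9, D=5.4, C=1.2, Q=3.9, E=6.2, G=7.4, H=2.2,
          I=6.0, L=10.0, K=4.7, M=2.4, F=3.9, P=4.7, S=5.8, T=5.4, W=1.3,
          Y=2.9, V=6.8)[aa20]

rand_protein <- function(n) {
  paste(c("M", sample(aa20, n - 1, replace = TRUE, prob = freq)), collapse = "")
}

set_residues <- function(p, fixes) {
  v <- strsplit(p, "")[[1]]
  v[as.integer(names(fixes))] <- unname(fixes)
  paste(v, collapse = "")
}

core <- data.frame(
  role_name = c("methylase", "hypothetical_2", "ankyrin_repeat_small",
                "terminase", "gpW", "hydrolase_orf6", "hydrolase_orf7",
                "portal", "s49_peptidase", "head_decoration",
                "major_capsid_E", "hypothetical_12", "tail_Z",
                "hypothetical_14", "baseplate_V", "PAAR", "baseplate_W",
                "baseplate_J", "tail_I", "hypothetical_20", "hypothetical_21",
                "DUF2924"),
  category = c("other", "other", "other", "packaging", "head", "lysis",
               "lysis", "head", "head", "head", "head", "other", "tail",
               "other", "baseplate", "baseplate", "baseplate", "baseplate",
               "tail", "other", "other", "other"),
  aa_len = c(410, 180, 220, 433, 120, 64, 175, 450, 300, 190, 360, 150, 200,
             160, 210, 95, 180, 310, 240, 140, 130, 230),
  stringsAsFactors = FALSE)

extra <- data.frame(
  role_name = c("ankyrin", "AAA_ATPase", "tape_measure", "recombinase",
                "IS110_transposase"),
  category = c("EAM", "EAM", "EAM", "regulatory", "other"),
  aa_len = c(3941, 717, 812, 350, 330),
  stringsAsFactors = FALSE)

panel <- rbind(core, extra)
panel$protein_seq <- vapply(panel$aa_len, rand_protein, character(1))

# residues dictated by the frameshift-locus codon layout
hyd6_fix <- c(`52`="A", `53`="E", `54`="D", `58`="L", `59`="N", `60`="K",
              `61`="F", `62`="Y", `63`="H", `64`="G")
hyd7_fix <- c(`2`="V", `3`="K", `4`="E", `5`="T", `6`="N", `7`="S", `8`="W",
              `10`="A", `11`="E", `12`="D",
              `30`="L", `31`="A", `32`="S", `33`="R", `34`="C", `35`="F",
              `36`="I", `37`="A",
              `150`="A", `151`="T", `152`="V", `153`="I", `154`="W",
              `155`="S", `156`="L", `157`="E")
i6 <- panel$role_name == "hydrolase_orf6"
i7 <- panel$role_name == "hydrolase_orf7"
panel$protein_seq[i6] <- set_residues(panel$protein_seq[i6], hyd6_fix)
panel$protein_seq[i7] <- set_residues(panel$protein_seq[i7], hyd7_fix)

foreign <- data.frame(
  role_name = c("mosquito_actin", "mosquito_histone_H3",
                "mosquito_tubulin_beta", "mosquito_ribosomal_P0",
                "mosquito_vitellogenin"),
  category = "other",
  aa_len = c(376, 136, 447, 317, 450),
  stringsAsFactors = FALSE)
foreign$protein_seq <- vapply(foreign$aa_len, rand_protein, character(1))

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write.table(panel[, c("role_name", "category", "protein_seq")],
            "inst/extdata/role_panel_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(foreign[, c("role_name", "category", "protein_seq")],
            "inst/extdata/foreign_panel_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(panel), "panel entries and", nrow(foreign), "foreign entries\n")
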