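#!/usr/bin/env Rscript
# Validation of the pedigree (PBLUP) and single-step genomic (ssGBLUP)
# evaluations: forward validation on the youngest genotyped cohort
# (adjusted-phenotype and LR-method statistics) and mid-parent validation of
# fillet yield. Variance components come from the REML run (02).

suppressPackageStartupMessages(library(troutGS))

ped <- read_pedigree("results/simdata/pedigree.csv")
data <- read_phenotypes("results/simdata/phenotypes.csv")
map <- read_snp_map("results/simdata/snp_map.csv")
geno <- read_genotypes_raw("results/simdata/genotypes.raw", map)
vc_tab <- read.delim("results/variance_components.tsv")
mk <- function(comp) {
  v <- vc_tab[vc_tab$component == comp, ]
  matrix(v$estimate[c(1, 2, 2, 3)], 2,
         dimnames = list(c("fy", "bw"), c("fy", "bw")))
}
vc <- vc_components(Su = mk("Su"), Sf = mk("Sf"), Se = mk("Se"))

cut <- max(as.numeric(data$hatch_year))
cat("Validating on the", cut, "cohort; training on earlier records\n")
vs <- validation_study(data, ped, vc, geno = geno, cut_year = cut)
cat(length(vs$validation_animals), "genotyped validation animals;",
    "mean inbreeding", round(vs$F_bar, 4), "\n\n")
print(vs$reports, row.names = FALSE)
write.table(vs$reports, "results/forward_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

r <- vs$reports
for (tr in c("fy", "bw")) {
  a_p <- r$value[r$model == "pblup" & r$method == "LR" & r$trait == tr &
                   r$statistic == "accuracy"]
  a_g <- r$value[r$model == "ssgblup" & r$method == "LR" & r$trait == tr &
                   r$statistic == "accuracy"]
  cat(sprintf("%s: LR accuracy PBLUP %.2f -> ssGBLUP %.2f (%+.0f%%)\n",
              toupper(tr), a_p, a_g, 100 * (a_g - a_p) / a_p))
}

# mid-parent validation of fillet yield on the last cohort's families
mp <- midparent_study(data, ped, vc, geno = geno, cut_year = cut)
mp_rows <- do.call(rbind, lapply(names(mp), function(m)
  do.call(rbind, lapply(names(mp[[m]]), function(b) {
    rep <- mp[[m]][[b]]
    data.frame(model = m, benchmark = b, n = rep$n, cor = rep$cor,
               b0 = rep$b0, b1 = rep$b1)
  }))))
cat("\nMid-parent validation (fillet yield):\n")
print(mp_rows, row.names = FALSE)
write.table(mp_rows, "results/midparent_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_validation_tsv(
  list(lr_fy_ssgblup = c(list(method = "LR_fy_ssgblup"),
                         as.list(setNames(
                           r$value[r$model == "ssgblup" & r$method == "LR" &
                                     r$trait == "fy"],
                           r$statistic[r$model == "ssgblup" &
                                         r$method == "LR" &
                                         r$trait == "fy"])),
                         list(n = length(vs$validation_animals)))),
  "results/validation_summary.tsv")
cat("Wrote results/forward_validation.tsv and results/midparent_validation.tsv\n")
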