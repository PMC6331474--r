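toy_pwm <- function(consensus, p = 0.94) {
  letters <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, length(letters), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(letters), match(letters, c("A", "C", "G", "T")))] <- p
  m
}

test_that("MEME and JASPAR motif files round-trip through the readers", {
  pwms <- list(TF_A = toy_pwm("ACGT"), TF_B = toy_pwm("GGATC"))
  f <- tempfile(fileext = ".meme")
  write_meme(pwms, f, background = c(0.3, 0.2, 0.2, 0.3))
  back <- read_meme(f)
  expect_equal(names(back), names(pwms))
  expect_equal(back$TF_A, pwms$TF_A, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(unname(attr(back, "background")), c(0.3, 0.2, 0.2, 0.3))
  fj <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TFX",
               "A [ 10  0  0 ]",
               "C [  0 10  0 ]",
               "G [  0  0 10 ]",
               "T [  0  0  0 ]"), fj)
  j <- read_jaspar(fj)
  expect_equal(unname(j$TFX[1, "A"]), 1)
  expect_equal(unname(j$TFX[3, "G"]), 1)
})

test_that("non-redundant library selection follows species then evidence", {
  rec <- function(tf, sp, ev, db, id)
    pwm_record(tf, toy_pwm("ACGTAC"), species = sp, evidence = ev,
               source_db = db, motif_id = id)
  lib <- build_nonredundant_library(list(
    rec("T1", "human", "experimental", "JASPAR", "a"),
    rec("T1", "mouse", "experimental", "HOCOMOCO", "b")))
  expect_equal(lib$records$T1$species, "human")
  # species outranks evidence
  lib2 <- build_nonredundant_library(list(
    rec("T1", "human", "computational", "CISBP", "a"),
    rec("T1", "mouse", "experimental", "HOCOMOCO", "b")))
  expect_equal(lib2$records$T1$species, "human")
  expect_equal(lib2$records$T1$evidence, "computational")
  expect_warning(
    lib3 <- build_nonredundant_library(list(
      rec("T1", "human", "experimental", "JASPAR", "a"),
      rec("T2", "other", "experimental", "JASPAR", "c"))),
    "dropped")
  expect_false("T2" %in% names(lib3$records))
})

test_that("library selection matches an exhaustive rule-table oracle", {
  set.seed(20)
  db_priority <- c("HOCOMOCO", "JASPAR", "Jolma2013", "CISBP")
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    recs <- lapply(seq_len(n), function(i)
      pwm_record("TF", toy_pwm("ACGTAC"),
                 species = sample(c("human", "mouse", "other"), 1),
                 evidence = sample(c("experimental", "computational"), 1),
                 source_db = sample(db_priority, 1),
                 motif_id = sprintf("m%02d", i)))
    ok <- vapply(recs, function(r) r$species != "other", logical(1))
    if (!any(ok)) {
      expect_warning(expect_error(build_nonredundant_library(recs),
                                  NA), "dropped")
      next
    }
    lib <- suppressWarnings(build_nonredundant_library(recs, db_priority))
    # oracle: sort by explicit rule table
    keep <- recs[ok]
    score <- vapply(keep, function(r)
      paste(match(r$species, c("human", "mouse")),
            match(r$evidence, c("experimental", "computational")),
            sprintf("%02d", match(r$source_db, db_priority)),
            r$motif_id), character(1))
    expect_equal(lib$records$TF$motif_id,
                 keep[[order(score)[1]]]$motif_id)
  }
})

test_that("log-odds scores follow the pseudocount formula", {
  uni <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(log_odds_matrix(uni, pseudocount = 0),
               matrix(0, 4, 4), ignore_attr = TRUE)
  det <- matrix(c(1, 0, 0, 0), 1, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(unname(log_odds_matrix(det, pseudocount = 0)[1, "A"]), 2)
  set.seed(23)
  pwm <- toy_pwm("ACGTTG", p = 0.7)
  bg <- c(0.2, 0.3, 0.3, 0.2)
  lom <- log_odds_matrix(pwm, bg, pseudocount = 0.1)
  want <- log2(((pwm[2, "C"] + 0.1 * 0.3) / 1.1) / 0.3)
  expect_equal(lom[2, "C"], want)
  expect_error(log_odds_matrix(pwm, c(0, 0.5, 0.25, 0.25)), "> 0")
})

test_that("DP p-values equal exhaustive enumeration for all fixture motifs", {
  consensi <- c("TGGCAA", "GACCTTG", "CTTAGGAC", "AGGTCAGG")
  bgs <- list(rep(0.25, 4), c(0.3, 0.2, 0.2, 0.3))
  for (cons in consensi) for (bg in bgs) {
    lom <- log_odds_matrix(toy_pwm(cons), bg, pseudocount = 0.1)
    tab <- exact_pvalue_table(lom, bg)
    ora <- oracle_exhaustive_pvalues(lom, bg)
    # evaluate at every distinct achievable score
    sc <- sort(unique(round(ora$scores, 9)))
    p_dp <- pwm_pvalue(tab, sc)
    p_ex <- vapply(sc, function(s)
      sum(ora$probs[ora$scores >= s - 1e-9]), numeric(1))
    expect_lt(max(abs(p_dp - p_ex)), 1e-4)
    expect_true(all(diff(p_dp) <= 1e-12))  # non-increasing in score
  }
})

test_that("a strict consensus motif has the closed-form consensus p-value", {
  det <- matrix(0, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  det[, "A"] <- 1
  lom <- log_odds_matrix(det, pseudocount = 0)
  tab <- exact_pvalue_table(lom)
  expect_equal(pwm_pvalue(tab, sum(apply(lom, 1, max))), (1 / 4)^3)
})

test_that("scanning finds planted motifs on both strands deterministically", {
  lib <- build_nonredundant_library(list(
    pwm_record("TFX", toy_pwm("CTTAGGAC"))))
  set.seed(31)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  s <- base
  substr(s, 38, 45) <- "CTTAGGAC"                     # + strand at offset 37
  substr(s, 91, 98) <- "GTCCTAAG"                     # reverse complement
  hits <- scan_sequences(c(reg1 = s), lib, background = rep(0.25, 4))
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_true(37 %in% plus$start)
  expect_true(90 %in% minus$start)
  expect_identical(hits, scan_sequences(c(reg1 = s), lib,
                                        background = rep(0.25, 4)))
  # reverse-complementing the sequence swaps strands and mirrors offsets
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  hrc <- scan_sequences(c(reg1 = rc), lib, background = rep(0.25, 4))
  expect_equal(sort(nchar(s) - 8 - hits$start), sort(hrc$start))
  expect_setequal(hrc$strand, setdiff(c("+", "-"), character(0)))
  # windows containing N are skipped; short sequences yield nothing
  expect_equal(nrow(scan_sequences(c(x = "ACGT"), lib)), 0)
  sN <- s; substr(sN, 38, 38) <- "N"
  hN <- scan_sequences(c(reg1 = sN), lib, background = rep(0.25, 4))
  expect_false(37 %in% hN$start[hN$strand == "+"])
})

test_that("ERE hits are counted per gene across its regions", {
  hits <- data.frame(region = c("r1", "r1", "r2", "r3"),
                     tf = c("ESR1", "ESR1", "ESR1", "OTHER"),
                     start = 1:4, stop = 9:12,
                     strand = "+", score = 1, pvalue = 1e-4)
  map <- data.frame(gene = c("g1", "g1", "g2"),
                    region = c("r1", "r2", "r3"))
  out <- ere_hits(hits, map)
  expect_equal(out[["g1"]], 3)
  expect_equal(out[["g2"]], 0)
  # invariant to region order
  expect_equal(ere_hits(hits[4:1, ], map), out)
  lib <- build_nonredundant_library(list(pwm_record("TFX",
                                                    toy_pwm("ACGTAC"))))
  expect_error(ere_hits(hits, map, library = lib), "missing")
})
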