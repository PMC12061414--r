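# Deterministic 20-record lab fixture covering every clinical bin boundary
# (values at 100/126 mg/dL FBG, 150/200 TG, 40 HDL, 200/240 TCHOL, etc.) and
# one missing insulin. Built inline so the fixture and its provenance live in
# one place.
labs20 <- function() {
  tibble::tibble(
    id = 1:20,
    sex = rep(c("M", "F"), 10),
    age = c(40, 69, 45, 50, 55, 60, 65, 41, 48, 52,
            57, 62, 67, 44, 49, 53, 58, 63, 68, 46),
    insulin = c(8.1, 12.0, 5.0, 20.25, 4.05, 10.0, NA, 15.0, 2.5, 30.0,
                7.0, 9.5, 11.1, 6.3, 18.0, 3.2, 25.0, 14.4, 8.8, 16.2),
    fbg = c(100, 126, 99, 125, 81, 110, 105, 126.5, 90, 200,
            95, 100.5, 118, 99.5, 130, 85, 160, 112, 101, 140),
    tg = c(150, 200, 149, 199, 100, 160, 120, 250, 80, 400,
           90, 151, 180, 149.5, 220, 70, 500, 170, 150.5, 210),
    hdl = c(50, 40, 39.5, 40.5, 60, 45, 55, 38, 70, 35,
            52, 48, 41, 49, 39, 65, 30, 44, 50.5, 42),
    tchol = c(200, 240, 199, 239, 180, 210, 195, 260, 170, 300,
              185, 201, 230, 198, 245, 160, 280, 215, 205, 250),
    hba1c = c(5.7, 6.4, 5.6, 6.3, 5.0, 5.9, 5.8, 6.5, 4.9, 8.2,
              5.2, 5.75, 6.1, 5.65, 6.6, 5.1, 7.5, 6.0, 5.72, 6.9),
    sbp = c(120, 140, 119, 139, 100, 125, 118, 150, 95, 170,
            110, 121, 135, 117, 145, 105, 160, 130, 122, 148),
    dbp = c(80, 90, 79, 89, 60, 82, 78, 95, 58, 105,
            70, 81, 88, 77, 92, 65, 100, 85, 80.5, 94)
  )
}

# Frozen oracle values for labs20(), computed independently from the raw
# fixture numbers with the defining formulas (HOMA-IR = insulin*FBG/405,
# TyG = ln(TG*FBG/2), TG/HDL, Friedewald LDL = TCHOL - HDL - TG/5).
labs20_oracle <- function() {
  list(
    homa_ir = c(2, 3.73333333333333, 1.22222222222222, 6.25, 0.81,
                2.71604938271605, NA, 4.68518518518519, 0.555555555555556,
                14.8148148148148, 1.64197530864198, 2.35740740740741,
                3.23407407407407, 1.54777777777778, 5.77777777777778,
                0.671604938271605, 9.87654320987654, 3.98222222222222,
                2.19456790123457, 5.6),
    tyg = c(8.9226582995244, 9.44145209293957, 8.9059189755201,
            9.42847138146685, 8.30647216010058, 9.0825070004663,
            8.74830491237962, 9.66855604546988, 8.1886891244442,
            10.5966347330961, 8.36053938137086, 8.93429038375411,
            9.27049429479593, 8.91430685643534, 9.568014816248,
            7.99799931797973, 10.5966347330961, 9.16115012778541,
            8.93593642047025, 9.59560277276683),
    tg_hdl = c(3, 5, 3.77215189873418, 4.91358024691358, 1.66666666666667,
               3.55555555555556, 2.18181818181818, 6.57894736842105,
               1.14285714285714, 11.4285714285714, 1.73076923076923,
               3.14583333333333, 4.39024390243902, 3.05102040816327,
               5.64102564102564, 1.07692307692308, 16.6666666666667,
               3.86363636363636, 2.98019801980198, 5),
    ldl = c(120, 160, 129.7, 158.7, 100, 133, 116, 172, 84, 185,
            115, 122.8, 153, 119.1, 162, 81, 150, 137, 124.4, 166),
    fbg_cat = c("Caution", "Danger", "Normal", "Caution", "Normal", "Caution",
                "Caution", "Danger", "Normal", "Danger", "Normal", "Caution",
                "Caution", "Normal", "Danger", "Normal", "Danger", "Caution",
                "Caution", "Danger"),
    tg_cat = c("Caution", "Danger", "Normal", "Caution", "Normal", "Caution",
               "Normal", "Danger", "Normal", "Danger", "Normal", "Caution",
               "Caution", "Normal", "Danger", "Normal", "Danger", "Caution",
               "Caution", "Danger"),
    hdl_cat = c("Normal", "Normal", "Danger", "Normal", "Normal", "Normal",
                "Normal", "Danger", "Normal", "Danger", "Normal", "Normal",
                "Normal", "Normal", "Danger", "Normal", "Danger", "Normal",
                "Normal", "Normal"),
    diabetes = c("no", "yes", "no", "no", "no", "no", "no", "yes", "no",
                 "yes", "no", "no", "no", "no", "yes", "no", "yes", "no",
                 "no", "yes"),
    dyslipidemia = c("no", "yes", "yes", "no", "no", "no", "no", "yes", "no",
                     "yes", "no", "no", "no", "no", "yes", "no", "yes", "no",
                     "no", "yes")
  )
}

# Small 4-node ground-truth network helpers used across structure tests
toy_chain_fit <- function() {
  dag <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  lv <- list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y"))
  cpts <- list(
    a = structure(matrix(c(0.7, 0.3), 1, 2,
                         dimnames = list(NULL, lv$a)), parents = character(0)),
    b = structure(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
                         dimnames = list(NULL, lv$b)), parents = "a"),
    c = structure(matrix(c(0.8, 0.4, 0.2, 0.6), 2, 2,
                         dimnames = list(NULL, lv$c)), parents = "b")
  )
  structure(list(dag = dag, cpts = cpts, levels = lv,
                 nlev = c(a = 2L, b = 2L, c = 2L), alpha = 0),
            class = "bn_fit", uniform_rows = integer(0))
}

# a deterministic discrete dataset with a clear a -> b dependence
toy_data <- function(n = 400, seed = 1) {
  withr::with_seed(seed, {
    a <- sample(c("x", "y"), n, replace = TRUE)
    b <- ifelse(runif(n) < ifelse(a == "x", 0.9, 0.15), "x", "y")
    c_ <- sample(c("x", "y"), n, replace = TRUE)
    tibble::tibble(a = a, b = b, c = c_)
  })
}
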