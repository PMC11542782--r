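# Curated seed lexicon of clinical-CRF-flavoured tokens used by the
# synthetic corpus generator. The contents are arbitrary (chosen to look
# like real form text: dates, pressures, doses, events) and documented as
# such; when a pool is exhausted the generator synthesizes deterministic
# variants (stem + number) so corpora of any size exist.

lex_shared_words <- c(
  "date", "of", "visit", "subject", "patient", "value", "result", "record",
  "please", "enter", "the", "if", "any", "unit", "units", "time", "at",
  "assessment", "baseline", "screening", "form", "number", "code", "yes",
  "no", "not", "done", "applicable", "other", "specify", "comments", "was",
  "first", "last", "start", "end", "per", "day", "total", "actual", "on",
  "prior", "current", "ongoing", "for", "this", "collection", "entry"
)

lex_topic_stems <- c(
  "adverse", "event", "severity", "serious", "outcome", "related", "action",
  "medication", "drug", "dose", "frequency", "route", "indication",
  "treatment", "therapy", "concomitant", "history", "condition", "diagnosis",
  "resolved", "surgery", "systolic", "diastolic", "blood", "pressure",
  "pulse", "heart", "rate", "temperature", "respiratory", "weight", "height",
  "birth", "sex", "gender", "race", "ethnicity", "age", "death",
  "randomization", "eligibility", "consent", "oral", "intravenous",
  "tablet", "capsule", "infusion", "mild", "moderate", "administration",
  "vital", "sign", "sitting", "standing", "supine", "arm", "position",
  "measurement", "reading", "examination", "onset", "stop", "continuing",
  "recovered", "fatal", "hospitalization", "intensity", "causality", "grade"
)

lex_oid_fragments <- c(
  "AE", "CM", "MH", "VS", "DM", "LB", "EX", "DS", "ADMIN", "LOG", "EVENT",
  "MED", "HIST", "SIGN", "DEMO", "CONC", "ADV", "VITAL", "DOSE", "FREQ",
  "DT", "DAT", "VAL", "RES", "CD", "NUM", "SEV", "REL", "OUT", "ACT",
  "STRT", "END", "TOT", "SYS", "DIA", "BP", "HR", "TEMP", "WT", "HT",
  "RAND", "ELIG", "BRTH", "AGT", "ACTL", "TRT", "RTE", "IND", "OCC", "YN"
)

lex_format_hints <- c(
  "(dd mmm yyyy)", "(MM/DD/YYYY)", "(ddddd.ddd)", "(dddddddd)", "(hh:mm)",
  "(mmHg)", "(kg)", "(cm)", "(bpm)", "(C)", "(%)", "(mg)", "(mL)",
  "(units/day)", "(GMT)", "(MMM dd yyyy)"
)

lex_sdtm_domains <- c("AE", "CM", "MH", "VS", "DM")
lex_sdtm_suffixes <- c(
  "STDTC", "ENDTC", "TRT", "TERM", "DECOD", "ORRES", "ORRESU", "TESTCD",
  "DOSE", "DOSU", "DOSFRQ", "SEV", "REL", "OUT", "OCCUR", "CAT", "BODSYS",
  "DTC", "BRTHDTC", "SEX", "RACE", "AGE", "ROUTE", "INDC", "ONGO"
)

# Draw n distinct items from a pool, synthesizing deterministic "<stem><k>"
# variants once the pool runs out.
draw_distinct <- function(pool, n, used = character()) {
  avail <- setdiff(pool, used)
  out <- if (length(avail) >= n) sample(avail, n) else avail
  k <- 1L
  while (length(out) < n) {
    cand <- paste0(sample(pool, 1L), k)
    if (!cand %in% c(out, used)) out <- c(out, cand)
    k <- k + 1L
  }
  out
}
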