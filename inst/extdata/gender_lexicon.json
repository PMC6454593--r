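{
  "Male": ["males", "male", "man", "men", "gay", "gays", "masculine"],
  "Female": ["females", "female", "woman", "women", "lesbians", "lesbian", "les", "feminine"],
  "Two_Gender": ["m/f", "m&f", "both genders", "two genders", "two-gender", "all genders", "all-gender"],
  "Biological": ["biologically", "biological", "cisgender"],
  "Transgender": ["transgender", "transsexual", "transsexuals", "transsexualism", "change sex", "changed sex", "sex changed", "change gender", "changed gender", "gender changed", "transgendered"],
  "Male_Abbreviation": ["msm", "msw", "msm/w", "msw/m", "ymsm"],
  "Partner": ["partner", "partners", "sexual partner", "sexual partners", "wife", "husband"],
  "Negation_Word": ["no", "not", "except", "besides", "rather", "rather than", "neither", "not identify as", "not identified as"]
}
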