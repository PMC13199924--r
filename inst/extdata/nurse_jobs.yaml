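# Nurse job-preference DCE instrument.
# Levels are ordered least -> most attractive; points anchor that order
# (0 = least, 1 = most attractive within the attribute).
attributes:
  - name: "Annual salary (brutto)"
    levels: ["65'000 - 74'999 CHF", "75'000 - 84'999 CHF", "85'000 - 95'000 CHF"]
    points: [0, 0.5, 1]
  - name: "Journey time to work (one-way, door-to-door)"
    levels: ["60 minutes", "30 minutes"]
    points: [0, 1]
  - name: "Weekly working hours (100% workload)"
    levels: ["42 hours", "38 hours"]
    points: [0, 1]
  - name: "Vacation days per year"
    levels: ["20 days", "30 days"]
    points: [0, 1]
  - name: "How often do nursing actions have to be omitted?"
    levels: ["Frequently", "Rarely"]
    points: [0, 1]
  - name: "How often do you work overtime or have to skip breaks?"
    levels: ["Several times a week", "Several times a month", "Never"]
    points: [0, 0.5, 1]
  - name: "Influence on the shift plan"
    levels: ["No", "Yes, I can specify 5 desired shifts per month",
             "Yes, I can write the entire shift plan myself"]
    points: [0, 0.5, 1]
  - name: "Supportive leadership - individual promotion of strengths and professional development"
    levels: ["No", "Yes"]
    points: [0, 1]
  - name: "Additional night/weekend shifts for a financial bonus (CHF 25 per hour)"
    levels: ["No", "Yes"]
    points: [0, 1]
design:
  J: 3
  S: 18
  n_blocks: 2
  balance_threshold: 4.5
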