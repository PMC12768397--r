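{
  "constructs": [
    {
      "construct": "EmotionRegulation",
      "empirical": 44.6,
      "theoretical": 20,
      "hybrid_printed": 32.3,
      "final_printed": 31
    },
    {
      "construct": "PersonalStress",
      "empirical": 16.3,
      "theoretical": 10,
      "hybrid_printed": 13.2,
      "final_printed": 13
    },
    {
      "construct": "SocialConnection",
      "empirical": 7.8,
      "theoretical": 18,
      "hybrid_printed": 12.9,
      "final_printed": 12
    },
    {
      "construct": "PerseverativeThinking",
      "empirical": 8.3,
      "theoretical": 14,
      "hybrid_printed": 11.2,
      "final_printed": 11
    },
    {
      "construct": "Sleep",
      "empirical": 6.9,
      "theoretical": 9,
      "hybrid_printed": 7.9,
      "final_printed": 8
    },
    {
      "construct": "DietaryIntake",
      "empirical": 6.2,
      "theoretical": 5,
      "hybrid_printed": 5.6,
      "final_printed": 5
    },
    {
      "construct": "Burnout",
      "empirical": 5.3,
      "theoretical": 5,
      "hybrid_printed": 5.2,
      "final_printed": 5
    },
    {
      "construct": "PhysicalActivity",
      "empirical": 0.2,
      "theoretical": 7,
      "hybrid_printed": 3.6,
      "final_printed": 5
    },
    {
      "construct": "WorkStress",
      "empirical": 1,
      "theoretical": 7,
      "hybrid_printed": 4,
      "final_printed": 5
    },
    {
      "construct": "PurposeProsociality",
      "empirical": 3.9,
      "theoretical": 5,
      "hybrid_printed": 4.5,
      "final_printed": 5
    }
  ],
  "priorities": {
    "CD-RISC": 25,
    "BRS": 22,
    "PSS-4": 18,
    "PHQ-8": 15,
    "GAD-7": 12,
    "WHO-5": 8
  },
  "reverse_criteria": ["PSS-4", "PHQ-8", "GAD-7"],
  "floor": 5
}
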