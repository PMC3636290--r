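# Four multiple-choice lower-back-pain scenarios in the trial's design:
# three with GRADE-graded evidence attached to every option, one (sick leave)
# without any evidence. Option lists and labels are a synthetic
# reconstruction consistent with the trial's description; the original
# questionnaires were not published.
scenarios:
  - scenario_id: imaging
    topic: "Medical imaging for acute nonspecific lower back pain"
    options:
      - option_id: no_routine_imaging
        label: "Do not order routine imaging; re-evaluate clinically"
        grade: high
        direction: pro
      - option_id: plain_xray
        label: "Order a plain lumbar radiograph"
        grade: moderate
        direction: contra
      - option_id: mri_scan
        label: "Order an MRI of the lumbar spine"
        grade: low
        direction: contra
      - option_id: ct_scan
        label: "Order a CT scan of the lumbar spine"
        grade: low
        direction: contra
      - option_id: bone_scan
        label: "Order a radionuclide bone scan"
        grade: very_low
        direction: contra
  - scenario_id: therapy
    topic: "Therapeutic options for acute nonspecific lower back pain"
    options:
      - option_id: stay_active
        label: "Advise to stay active and continue daily activities"
        grade: high
        direction: pro
      - option_id: exercise_therapy
        label: "Refer for supervised exercise therapy"
        grade: moderate
        direction: pro
      - option_id: spinal_manipulation
        label: "Refer for spinal manipulation"
        grade: low
        direction: pro
      - option_id: bed_rest
        label: "Prescribe bed rest until the pain subsides"
        grade: moderate
        direction: contra
  - scenario_id: drugs
    topic: "Drug treatment for acute nonspecific lower back pain"
    options:
      - option_id: paracetamol
        label: "Start paracetamol at regular intervals"
        grade: high
        direction: pro
      - option_id: nsaid
        label: "Start a short course of an NSAID"
        grade: moderate
        direction: pro
      - option_id: muscle_relaxant
        label: "Start a muscle relaxant"
        grade: low
        direction: pro
      - option_id: weak_opioid
        label: "Start a weak opioid"
        grade: low
        direction: contra
      - option_id: antidepressant
        label: "Start a tricyclic antidepressant"
        grade: very_low
        direction: contra
  - scenario_id: sick_leave
    topic: "Sick leave advice for acute nonspecific lower back pain"
    options:
      - option_id: no_sick_leave
        label: "No sick leave; continue working with adapted tasks"
        grade: absent
        direction: none
      - option_id: few_days
        label: "A few days of sick leave, then gradual return"
        grade: absent
        direction: none
      - option_id: one_week
        label: "One week of sick leave"
        grade: absent
        direction: none
      - option_id: until_painfree
        label: "Sick leave until completely pain free"
        grade: absent
        direction: none
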