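# Default preferred-term -> AEFI-group mapping.
# Each of the 19 otolaryngologic groups is seeded with the MedDRA preferred
# terms literally named in its label plus close lexical variants; supply a
# fuller curated PT list through the same structure for production use.
group_names:
  - "Hearing loss"
  - "Tinnitus (Ringing in the ears)"
  - "Ear infections (Otitis Media)"
  - "Meniere's disease"
  - "Vestibular neuronitis"
  - "Dizziness or vertigo"
  - "Sinusitis"
  - "Rhinitis (Allergic and Non-allergic)"
  - "Epistaxis"
  - "Anosmia"
  - "Nasal polyps"
  - "Snoring or difficulty breathing through the nose and sleep apnea"
  - "Allergies"
  - "Tonsillitis"
  - "Laryngitis"
  - "Vocal cord polyps and nodules"
  - "Laryngopharyngeal reflux (Acid Reflux)"
  - "Epiglottitis"
  - "Pharyngitis"
groups:
  "Hearing loss":
    - Hypoacusis
    - Deafness
    - Deafness unilateral
    - Sudden hearing loss
  "Tinnitus (Ringing in the ears)":
    - Tinnitus
    - Tinnitus aggravated
  "Ear infections (Otitis Media)":
    - Otitis media
    - Otitis media acute
    - Ear infection
  "Meniere's disease":
    - Meniere's disease
  "Vestibular neuronitis":
    - Vestibular neuronitis
    - Neuronitis vestibular
  "Dizziness or vertigo":
    - Dizziness
    - Vertigo
    - Vertigo positional
  "Sinusitis":
    - Sinusitis
    - Acute sinusitis
    - Chronic sinusitis
  "Rhinitis (Allergic and Non-allergic)":
    - Rhinitis
    - Rhinitis allergic
  "Epistaxis":
    - Epistaxis
  "Anosmia":
    - Anosmia
    - Hyposmia
  "Nasal polyps":
    - Nasal polyps
  "Snoring or difficulty breathing through the nose and sleep apnea":
    - Snoring
    - Nasal obstruction
    - Sleep apnoea syndrome
  "Allergies":
    - Hypersensitivity
    - Seasonal allergy
  "Tonsillitis":
    - Tonsillitis
  "Laryngitis":
    - Laryngitis
  "Vocal cord polyps and nodules":
    - Vocal cord polyp
    - Vocal cord nodule
  "Laryngopharyngeal reflux (Acid Reflux)":
    - Laryngopharyngeal reflux
    - Gastrooesophageal reflux disease
  "Epiglottitis":
    - Epiglottitis
  "Pharyngitis":
    - Pharyngitis
    - Oropharyngeal pain
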