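dataset_id:
  type: id
  mandatory: yes
round:
  type: enum
  levels:
  - r1
  - r2
  mandatory: yes
respondent_id:
  type: id
  mandatory: yes
respondent_is_owner:
  type: flag
  mandatory: no
species:
  type: multi
  levels:
  - cattle
  - swine
  - poultry
  - salmonids
  mandatory: no
language_status:
  type: enum
  levels:
  - english
  - not_english
  - translated
  mandatory: no
content_types:
  type: multi
  levels:
  - laboratory_results
  - biosecurity
  - production_results
  - treatment
  - clinical_observation
  - animal_movements
  - economic
  - behaviour
  mandatory: no
purposes:
  type: multi
  levels:
  - production_information
  - surveillance
  - legislation
  - lab_activities
  - other_business
  - research_integration
  mandatory: no
collection_sources:
  type: enum
  levels:
  - single_source
  - multiple_same_type
  - multiple_different_type
  - unreported
  mandatory: no
collection_mode:
  type: enum
  levels:
  - automated
  - manual
  - unreported
  mandatory: no
storage_format:
  type: enum
  levels:
  - relational_database
  - spreadsheet_collection
  - single_spreadsheet
  - pdf_collection
  mandatory: no
quality_practices:
  type: multi
  levels:
  - closed_formats
  - collector_training
  - manual_checks
  - automated_checks
  - inspection_verification
  - feedback_loops
  - standards_procedures
  mandatory: no
contains_personal_data:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
data_subject_identified:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
data_subject_documented:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
data_controller_identified:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
data_controller_documented:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
data_owner_identified:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
data_identifier_present:
  type: flag
  mandatory: no
data_identifying_elements:
  type: multi
  levels:
  - name
  - version_or_release_date
  - responsible_organisation
  mandatory: no
metadata_identifier_present:
  type: flag
  mandatory: no
metadata_identifying_elements:
  type: multi
  levels:
  - name
  - version_or_release_date
  - responsible_organisation
  mandatory: no
metadata_exist:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
metadata_link_update:
  type: enum
  levels:
  - automatic
  - manual
  - none_or_unknown
  mandatory: no
metadata_structure:
  type: enum
  levels:
  - standard_schema
  - documented
  - undocumented
  mandatory: no
metadata_vocabulary:
  type: enum
  levels:
  - standard
  - retrievable_glossary
  - collaborative
  - owner_defined
  - unknown
  mandatory: no
metadata_access_mode:
  type: enum
  levels:
  - documented_protocol
  - url
  - none
  mandatory: no
data_access_mode:
  type: enum
  levels:
  - documented_protocol
  - url
  - none
  mandatory: no
data_structure_documented:
  type: tristate
  levels:
  - 'yes'
  - 'no'
  - unknown
  mandatory: no
data_vocabulary_practice:
  type: enum
  levels:
  - standard
  - retrievable_glossary
  - collaborative
  - owner_defined
  - unknown
  mandatory: no
rich_metadata_elements:
  type: enum
  levels:
  - all_available
  - one_missing
  - more_missing
  mandatory: no
process_documentation:
  type: enum
  levels:
  - full
  - partial
  - none
  mandatory: no
licence_status:
  type: enum
  levels:
  - data_and_metadata
  - data_only
  - none
  mandatory: no
consent_publication:
  type: flag
  mandatory: no
consent_consortium:
  type: enum
  levels:
  - 'yes'
  - conditional
  - 'no'
  mandatory: no
consent_repository:
  type: flag
  mandatory: no
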