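rates:
  wage_per_hr: 25.0
  vehicle_per_km: 0.77
  return_trip_km: 130.0
  return_trip_hr: 2.0
  circuit_hr: 0.75
design:
  n_stations: 40.0
  n_occasions: 6.0
  count_duration_min: 15.0
  years: 2.0
options:
- option_name: MONO-VISUAL
  device_price: 300.0
  units: 40.0
  program_min_per_unit: 2.5
  program_accrual: per_year
  deploy_min_per_unit: 2.0
  deploy_accrual: per_year
  wage_trips_per_year: 1.0
  vehicle_trips_per_year: 2.0
  circuits_per_year: 2.0
  per_observer_travel: no
  observers_per_vehicle: 5.0
  processing_hr_per_file: 0.1
  counting_from_duration: no
- option_name: MONO-AUDIBLE
  device_price: 300.0
  units: 40.0
  program_min_per_unit: 2.5
  program_accrual: per_year
  deploy_min_per_unit: 2.0
  deploy_accrual: per_year
  wage_trips_per_year: 1.0
  vehicle_trips_per_year: 2.0
  circuits_per_year: 2.0
  per_observer_travel: no
  observers_per_vehicle: 5.0
  processing_hr_per_file: 0.25
  counting_from_duration: no
- option_name: STEREO-VISUAL
  device_price: 600.0
  units: 40.0
  program_min_per_unit: 3.0
  program_accrual: per_occasion
  deploy_min_per_unit: 10.0
  deploy_accrual: per_year
  wage_trips_per_year: 6.0
  vehicle_trips_per_year: 6.0
  circuits_per_year: 6.0
  per_observer_travel: no
  observers_per_vehicle: 5.0
  processing_hr_per_file: 0.1
  counting_from_duration: no
  year2_vehicle_override: 554.0
- option_name: STEREO-AUDIBLE
  device_price: 600.0
  units: 40.0
  program_min_per_unit: 3.0
  program_accrual: per_occasion
  deploy_min_per_unit: 10.0
  deploy_accrual: per_year
  wage_trips_per_year: 6.0
  vehicle_trips_per_year: 6.0
  circuits_per_year: 6.0
  per_observer_travel: no
  observers_per_vehicle: 5.0
  processing_hr_per_file: 0.25
  counting_from_duration: no
  year2_vehicle_override: 554.0
- option_name: OBS
  device_price: 0.0
  units: 40.0
  program_min_per_unit: 30.0
  program_accrual: per_occasion
  deploy_min_per_unit: 1.0
  deploy_accrual: per_year
  wage_trips_per_year: 6.0
  vehicle_trips_per_year: 6.0
  circuits_per_year: 6.0
  per_observer_travel: yes
  observers_per_vehicle: 5.0
  processing_hr_per_file: .na.real
  counting_from_duration: yes
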